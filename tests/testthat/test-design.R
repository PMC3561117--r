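# Design metrics: distinct-primer cost, interval-union coverage, reuse
# histogram, validity checking

# a small hand catalogue: F binds forward at 0 and 120 on g1; R1/R2 bind
# reverse ending at 100 and 220
P_F <- paste0(strrep("A", 10), strrep("G", 10))
P_R1 <- strrep("TC", 10)        # no complementarity to P_F
P_R2 <- paste0("TT", strrep("CTT", 6))
hand_catalog <- function() {
  fake_catalog(c(P_F, P_R1, P_R2),
               data.frame(cand = c(1L, 1L, 2L, 3L),
                          gene = 1L,
                          start = c(0L, 120L, 80L, 200L),
                          strand = c("+", "+", "-", "-")))
}
hand_design <- function(amps_rows) {
  genes <- gene_set(c(g1 = rand_oligo(300)))
  cfg <- primer_config()
  m <- if (length(amps_rows)) do.call(rbind, amps_rows) else
    matrix(integer(0), ncol = 4)
  primertile:::new_design(list(m), hand_catalog(), genes, cfg)
}

test_that("cost sums distinct primer lengths once (reuse is free)", {
  set.seed(41)
  expect_identical(design_cost(hand_design(list())), 0L)
  d1 <- hand_design(list(c(0L, 100L, 1L, 2L)))
  expect_identical(design_cost(d1), 40L)
  # second amplicon reuses F: only R2 adds to the bill
  d2 <- hand_design(list(c(0L, 100L, 1L, 2L), c(120L, 220L, 1L, 3L)))
  expect_identical(design_cost(d2), 60L)
})

test_that("coverage is the per-gene union of amplicon intervals", {
  set.seed(41)
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(50L, 150L, 1L, 3L)))
  expect_identical(design_coverage(d), 150L)
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(120L, 220L, 1L, 3L)))
  expect_identical(design_coverage(d), 200L)
  expect_identical(design_coverage(hand_design(list())), 0L)
})

test_that("cost per covered base reproduces printed design economics", {
  expect_equal(cost_per_covered_base(197, 958), 0.21)
  expect_equal(cost_per_covered_base(25284, 39240), 0.64)
  expect_error(cost_per_covered_base(100, 0), "zero coverage")
})

test_that("reuse histogram counts uses per distinct primer", {
  set.seed(41)
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(120L, 220L, 1L, 3L)))
  h <- redundancy_histogram(d)
  expect_identical(h$histogram, c(`1` = 2L, `2` = 1L))
  expect_identical(h$n_distinct, 3L)
  expect_identical(h$no_reuse_total, 4L)     # 2*1 + 1*2
  expect_equal(h$reduction_pct, 25)
  # all single-use: no reduction
  d1 <- hand_design(list(c(0L, 100L, 1L, 2L)))
  expect_equal(redundancy_histogram(d1)$reduction_pct, 0)
})

test_that("histogram identities hold on optimizer output", {
  fx <- generate_gene_set(n_genes = 4, length = 400, n_shared_sites = 2,
                          site_multiplicity = 3, snp_rate = 0, seed = 43)
  cfg <- primer_config(tm_min = 60, tm_max = 60, n_iterations = 150,
                       rng_seed = 7)
  ct <- prepare_candidates(fx$genes, 60L, cfg, fx$background)
  d <- run_optimization(fx$genes, ct, cfg, trace = FALSE)$design
  h <- redundancy_histogram(d)
  ids <- primertile:::.design_ids(d$amps)
  expect_identical(sum(h$histogram), length(unique(ids)))
  expect_identical(h$no_reuse_total, length(ids))
  expect_identical(design_cost(d),
                   sum(d$catalog$length[unique(ids)]))   # Eq-style re-sum
})

test_that("validity checking flags constraint violations, never throws", {
  set.seed(41)
  # amplicon longer than amplicon_max
  d <- hand_design(list(c(0L, 100L, 1L, 2L)))
  d$amps[[1]][1, 2] <- 301L
  v <- validate_design(d)
  expect_false(v$ok)
  expect_true("amplicon_length" %in% v$violations$type)
  # duplicated primer pair
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(0L, 100L, 1L, 2L)))
  v <- validate_design(d)
  expect_true("pair_duplicate" %in% v$violations$type)
  # forward locus without a binding site
  d <- hand_design(list(c(10L, 110L, 1L, 2L)))
  v <- validate_design(d)
  expect_true(all(c("fwd_site", "rev_site") %in% v$violations$type))
  # intact design passes
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(120L, 220L, 1L, 3L)))
  expect_true(validate_design(d)$ok)
})

test_that("gaps beyond max_gap warn without invalidating", {
  set.seed(41)
  d <- hand_design(list(c(0L, 100L, 1L, 2L), c(120L, 220L, 1L, 3L)))
  v <- validate_design(d)     # 20 bp gap > default max_gap 10
  expect_true(v$ok)
  expect_true("gap" %in% v$warnings$type)
})
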