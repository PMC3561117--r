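# Candidate enumeration, SNP constraints, background counts, degenerate
# generalization, weighting

cfg0 <- primer_config(tm_min = 50, tm_max = 70)

test_that("enumeration equals a brute-force both-strand scan", {
  set.seed(21)
  genes <- gene_set(c(gA = rand_oligo(60), gB = rand_oligo(45)))
  for (t in c(52L, 60L, 66L)) {
    ct <- enumerate_candidates(genes, t, cfg0)
    ref <- bf_enumerate(genes$consensus, t, cfg0$primer_len_min,
                        cfg0$primer_len_max)
    expect_setequal(ct$seq, unique(ref$seq))
    # per-candidate site lists and redundancy match the scan
    for (k in seq_along(ct$seq)) {
      hits <- ref[ref$seq == ct$seq[k], ]
      s <- ct$sites[ct$sites$cand == k, ]
      expect_identical(ct$redundancy[k], nrow(hits))
      expect_setequal(paste(s$gene, s$start, s$strand),
                      paste(hits$gene, hits$start, hits$strand))
    }
    expect_true(all(round(ct$tm) == t))
    expect_true(all(ct$length >= 18 & ct$length <= 27))
  }
})

test_that("an empty gene set yields an empty catalogue", {
  genes <- gene_set(setNames(character(0), character(0)))
  ct <- enumerate_candidates(genes, 60L, cfg0)
  expect_length(ct$seq, 0)
})

test_that("a motif planted at three loci becomes one candidate with redundancy 3", {
  fx <- generate_gene_set(n_genes = 4, length = 300, n_shared_sites = 1,
                          site_multiplicity = 3, snp_rate = 0, seed = 31,
                          motif_tm = 60)
  motif <- fx$truth$motifs$motif[1]
  ct <- enumerate_candidates(fx$genes, 60L, cfg0)
  k <- match(motif, ct$seq)
  expect_false(is.na(k))
  expect_identical(ct$redundancy[k], 3L)
  # ... and the reverse complement likewise primes all three loci
  krc <- match(bf_revcomp(motif), ct$seq)
  expect_identical(ct$redundancy[krc], 3L)
})

test_that("footprints containing N are never enumerated", {
  genes <- gene_set(c(g = paste0(rand_oligo(30), "N", rand_oligo(30))))
  ct <- enumerate_candidates(genes, 60L, cfg0)
  if (length(ct$seq)) {
    s <- ct$sites
    expect_true(all(s$start + ct$length[s$cand] <= 30 | s$start >= 31))
  }
  expect_false(any(grepl("N", ct$seq)))
})

test_that("SNP columns force W/S or invalidate the footprint", {
  set.seed(22)
  base <- rand_oligo(60)
  exc <- base
  substr(exc, 30, 30) <- if (substr(base, 30, 30) %in% c("A", "T")) "W" else "S"
  genes <- gene_set(c(g = base), c(g = exc))
  r <- apply_snp_constraints(genes, "g", 20, 20)
  expect_true(r$valid)
  expect_identical(r$n_forced, 1L)
  expect_identical(substr(r$seq, 10, 10),
                   if (substr(base, 30, 30) %in% c("A", "T")) "W" else "S")
  # non-neutral code ({A,G} = R) invalidates
  exc2 <- base
  substr(exc2, 30, 30) <- "R"
  substr(base, 30, 30) <- "A"      # ensure consensus base in {A,G}
  genes2 <- gene_set(c(g = base), c(g = exc2))
  r2 <- apply_snp_constraints(genes2, "g", 20, 20)
  expect_false(r2$valid)
  # outside the footprint: untouched
  r3 <- apply_snp_constraints(genes2, "g", 0, 20)
  expect_true(r3$valid)
  expect_identical(r3$seq, substr(base, 1, 20))
  expect_identical(r3$n_forced, 0L)
  # no exceptions sequence at all: unchanged and valid
  genes3 <- gene_set(c(g = base))
  r4 <- apply_snp_constraints(genes3, "g", 20, 20, strand = "-")
  expect_true(r4$valid)
  expect_identical(r4$seq, bf_revcomp(substr(base, 21, 40)))
})

test_that("enumerated candidates agree with apply_snp_constraints on SNP genes", {
  fx <- generate_gene_set(n_genes = 2, length = 250, n_shared_sites = 0,
                          snp_rate = 0.02, seed = 33)
  ct <- enumerate_candidates(fx$genes, 60L, cfg0)
  s <- ct$sites
  for (k in head(order(-ct$n_degenerate), 10)) {
    i <- which(s$cand == k)[1]
    r <- apply_snp_constraints(fx$genes, fx$genes$id[s$gene[i]], s$start[i],
                               ct$length[k], s$strand[i])
    expect_true(r$valid)
    expect_identical(r$seq, ct$seq[k])
    expect_identical(r$n_forced, ct$n_degenerate[k])
  }
})

test_that("background occurrence counts match brute force and bound redundancy", {
  set.seed(23)
  genes <- gene_set(c(g = rand_oligo(80)))
  ct <- enumerate_candidates(genes, 60L, cfg0)
  expect_gt(length(ct$seq), 2)
  bg <- c(b1 = rand_oligo(300), b2 = rand_oligo(200))
  counts <- count_background_occurrences(ct, bg)
  for (k in seq_len(min(8, length(ct$seq))))
    expect_identical(counts[k], bf_count(ct$seq[k], unname(bg)))

  # a screened primer later planted 11 times (max_redundancy 10) is discarded
  kept0 <- prepare_candidates(genes, 60L, cfg0, bg)
  p <- kept0$seq[kept0$n_degenerate == 0][1]
  expect_true(p %in% kept0$seq)
  bg11 <- c(bg, planted = paste(rep(c(p, rand_oligo(10)), 11), collapse = ""))
  c11 <- count_background_occurrences(ct, bg11)
  expect_gte(c11[match(p, ct$seq)], 11L)
  kept <- prepare_candidates(genes, 60L, cfg0, bg11)
  expect_false(p %in% kept$seq)

  # degenerate candidates sum matches over both expansions
  deg <- chartr("A", "W", p)
  if (primertile:::.n_degenerate(deg) %in% 1:3) {
    fake <- fake_catalog(deg, data.frame(cand = 1L, gene = 1L, start = 0L,
                                         strand = "+"))
    expect_identical(count_background_occurrences(fake, bg),
                     bf_count(deg, unname(bg)))
  }
})

test_that("degenerate generalization merges near-identical candidates", {
  # two 18-mers differing at one A/T position, each with one locus
  core <- strrep("G", 16)                # shared, hairpin-free
  s1 <- paste0("AA", core)
  s2 <- paste0("AT", core)
  g <- gene_set(c(g1 = paste0(s1, strrep("A", 30)),
                  g2 = paste0(s2, strrep("T", 30))))
  t <- round(bf_tm(s1))
  ct <- enumerate_candidates(g, t, cfg0)
  expect_true(all(c(s1, s2) %in% ct$seq))
  aug <- generate_degenerates(ct, cfg0)
  dseq <- paste0("AW", core)
  k <- match(dseq, aug$seq)
  expect_false(is.na(k))
  expect_identical(aug$n_degenerate[k], 1L)
  # merged sites: union of both members' loci
  expect_gte(aug$redundancy[k],
             ct$redundancy[match(s1, ct$seq)] +
               ct$redundancy[match(s2, ct$seq)])
})

test_that("max_degeneracy 0 disables generalization", {
  set.seed(24)
  genes <- gene_set(c(g = rand_oligo(120)))
  cfg <- primer_config(max_degeneracy = 0)
  ct <- enumerate_candidates(genes, 60L, cfg)
  expect_identical(generate_degenerates(ct, cfg)$seq, ct$seq)
})

test_that("retained degenerates equal a brute-force generate-and-test oracle", {
  set.seed(25)
  # small catalogue with planted near-duplicates
  words <- c("AAGGGGGGTTGGGGGGAA", "AAGGGGGGTAGGGGGGAA",
             "AAGGGGGGTTGGGGGGTA", "TTAAATTTAATTTAAATT")
  genes <- gene_set(setNames(
    paste0(words, vapply(seq_along(words), function(i) rand_oligo(25),
                         character(1))),
    paste0("g", seq_along(words))))
  cfgd <- primer_config(max_degeneracy = 2)   # pair oracle is then complete
  t <- round(bf_tm(words[1]))
  ct <- enumerate_candidates(genes, t, cfgd)
  aug <- generate_degenerates(ct, cfgd)
  new_deg <- setdiff(aug$seq, ct$seq)
  # oracle: try every W/S generalization of every candidate pair
  expected <- character(0)
  for (a in seq_along(ct$seq)) for (b in seq_along(ct$seq)) {
    if (a >= b || ct$length[a] != ct$length[b]) next
    ca <- strsplit(ct$seq[a], "")[[1]]; cb <- strsplit(ct$seq[b], "")[[1]]
    diff <- which(ca != cb)
    if (length(diff) == 0 || length(diff) > 2) next
    ok <- all((ca[diff] %in% c("A", "T", "W") & cb[diff] %in% c("A", "T", "W")) |
                (ca[diff] %in% c("C", "G", "S") & cb[diff] %in% c("C", "G", "S")))
    if (!ok) next
    m <- ca
    m[diff] <- ifelse(ca[diff] %in% c("A", "T", "W"), "W", "S")
    d <- paste(m, collapse = "")
    if (primertile:::.n_degenerate(d) <= 2 &&
        !check_hairpin(d) && !check_dimer(d, d))
      expected <- c(expected, d)
  }
  expect_setequal(new_deg, setdiff(unique(expected), ct$seq))
})

test_that("primer weighting is a deterministic total order", {
  sites <- data.frame(cand = c(1L, 1L, 1L, 2L, 2L, 3L, 4L),
                      gene = 1L, start = 0:6, strand = "+")
  ct <- fake_catalog(c("AAAAAAAAAAAAAAAAAAWG", "GGGGGGGGGGGGGGGGGGGG",
                       "CCCCCCCCCCCCCCCCCCCC", "AAAAAAAAAAAAAAAAAAAA"),
                     sites)
  r <- primer_weight(ct)
  # redundancy 3 / degeneracy 1 outranks redundancy 2 / degeneracy 0
  expect_lt(r[1], r[2])
  # equal redundancy and degeneracy: lexicographically smaller first
  expect_lt(r[4], r[3])
  # sorting is idempotent and total
  expect_setequal(r, seq_along(ct$seq))
  expect_identical(primer_weight(ct), r)
})
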