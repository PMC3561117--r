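# Initial design construction, greedy proposals, scheduling, acceptance,
# nested removal, the optimization loop and the exhaustive oracle

fx_small <- generate_gene_set(n_genes = 3, length = 400, n_shared_sites = 2,
                              site_multiplicity = 3, snp_rate = 0, seed = 51)
cfg_small <- primer_config(tm_min = 60, tm_max = 60, n_iterations = 400,
                           rng_seed = 9)
cat_small <- prepare_candidates(fx_small$genes, 60L, cfg_small,
                                fx_small$background)

test_that("initial designs obey amplicon constraints and are reproducible", {
  set.seed(1)
  d <- build_initial_design(fx_small$genes, cat_small, cfg_small)
  for (m in d$amps) {
    if (!nrow(m)) next
    len <- m[, 2] - m[, 1]
    expect_true(all(len >= cfg_small$amplicon_min &
                      len <= cfg_small$amplicon_max))
  }
  expect_lte(design_coverage(d), sum(fx_small$genes$length))
  expect_true(validate_design(d)$ok)
  set.seed(77)
  d1 <- build_initial_design(fx_small$genes, cat_small, cfg_small)
  set.seed(77)
  d2 <- build_initial_design(fx_small$genes, cat_small, cfg_small)
  expect_identical(d1$amps, d2$amps)
})

test_that("initial slack: overlap 30 yields at least as many amplicons and cost", {
  fx <- generate_gene_set(n_genes = 3, length = 600, n_shared_sites = 0,
                          snp_rate = 0, seed = 52)
  cfg0 <- primer_config(tm_min = 60, tm_max = 60, initial_overlap = 0)
  cfg30 <- primer_config(tm_min = 60, tm_max = 60, initial_overlap = 30)
  ct <- prepare_candidates(fx$genes, 60L, cfg0)
  n0 <- c0 <- n30 <- c30 <- numeric(5)
  for (i in 1:5) {
    set.seed(i)
    d0 <- build_initial_design(fx$genes, ct, cfg0)
    set.seed(i)
    d30 <- build_initial_design(fx$genes, ct, cfg30)
    n0[i] <- sum(vapply(d0$amps, nrow, integer(1)))
    n30[i] <- sum(vapply(d30$amps, nrow, integer(1)))
    c0[i] <- design_cost(d0); c30[i] <- design_cost(d30)
  }
  expect_gte(mean(n30), mean(n0))
  expect_gte(mean(c30), mean(c0))
})

test_that("proposals stay valid; per-gene refinement is local", {
  set.seed(2)
  d <- build_initial_design(fx_small$genes, cat_small, cfg_small)
  for (rep in 1:10) {
    p1 <- propose_method1_global(d)
    p2 <- propose_method2_gene(d)
    p3 <- propose_method3_reposition(d)
    expect_true(validate_design(p1)$ok)
    expect_true(validate_design(p2)$ok)
    expect_true(validate_design(p3)$ok)
    expect_lte(sum(vapply(seq_along(d$amps), function(g)
      !identical(d$amps[[g]], p2$amps[[g]]), logical(1))), 1L)
  }
})

test_that("repositioning eventually proposes every reachable alternative site", {
  set.seed(3)
  # one gene, one amplicon: enumerate the alternatives the proposal can reach
  fx1 <- generate_gene_set(n_genes = 1, length = 150, n_shared_sites = 0,
                           snp_rate = 0, seed = 53)
  cfg1 <- primer_config(tm_min = 58, tm_max = 58, n_iterations = 100,
                        amplicon_min = 100)
  ct1 <- prepare_candidates(fx1$genes, 58L, cfg1)
  d <- build_initial_design(fx1$genes, ct1, cfg1)
  expect_identical(sum(vapply(d$amps, nrow, integer(1))), 1L)
  seen <- character(0)
  for (i in 1:1000) {
    p <- propose_method3_reposition(d)
    seen <- union(seen, paste(p$amps[[1]][, 1], p$amps[[1]][, 2]))
  }
  s <- d$amps[[1]][1, 1]; e <- d$amps[[1]][1, 2]
  fid <- d$amps[[1]][1, 3]; rid <- d$amps[[1]][1, 4]
  lk <- primertile:::.build_lookup(ct1, fx1$genes, cfg1)
  pg <- lk$per_gene[[1]]
  admissible_fwd <- pg$fs[e - pg$fs >= cfg1$amplicon_min &
                            e - pg$fs <= cfg1$amplicon_max &
    vapply(pg$fc, function(f) ct1$seq[f] != ct1$seq[rid] &&
             !check_dimer(ct1$seq[f], ct1$seq[rid]), logical(1))]
  admissible_rev <- pg$re[pg$re - s >= cfg1$amplicon_min &
                            pg$re - s <= cfg1$amplicon_max &
    vapply(pg$rc, function(r) ct1$seq[fid] != ct1$seq[r] &&
             !check_dimer(ct1$seq[fid], ct1$seq[r]), logical(1))]
  reachable <- unique(c(paste(admissible_fwd, e), paste(s, admissible_rev)))
  expect_true(all(reachable %in% seen))
})

test_that("method scheduling follows the iteration thirds", {
  cfg <- primer_config(n_iterations = 9999)
  cfg$weight_greedy <- FALSE
  set.seed(4)
  draws <- vapply(1:3000, function(i) choose_method(0L, cfg), integer(1))
  expect_true(all(abs(tabulate(draws, 3) / 3000 - 1 / 3) < 0.05))
  cfg$weight_greedy <- TRUE
  d0 <- vapply(1:3000, function(i) choose_method(0L, cfg), integer(1))
  expect_identical(which.max(tabulate(d0, 3)), 1L)
  d9 <- vapply(1:3000, function(i) choose_method(9000L, cfg), integer(1))
  f3 <- mean(d9 == 3)
  expect_lt(abs(f3 - 0.8), 0.05)
  expect_true(all(1:3 %in% d9))            # all methods always reachable
})

test_that("Metropolis rule: downhill always, uphill at exp(-dS*H)", {
  set.seed(5)
  expect_true(all(metropolis_accept(rep(100, 50), rep(99, 50), H = 5)))
  expect_true(all(metropolis_accept(rep(100, 50), rep(100, 50), H = 5)))
  acc <- metropolis_accept(rep(0, 1e5), rep(10, 1e5), H = 0.2)
  expect_lt(abs(mean(acc) - exp(-2)), 3 * sqrt(exp(-2) / 1e5))
  # fraction mode accepts a fixed share of uphill proposals
  accf <- metropolis_accept(rep(0, 1e5), rep(10, 1e5), H = 0.3,
                            mode = "fraction")
  expect_lt(abs(mean(accf) - 0.3), 0.02)
})

test_that("nested amplicons are removed at the configured rate", {
  set.seed(6)
  # outer [0,220), nested [50,150)
  P_O1 <- strrep("AG", 10); P_O2 <- strrep("TC", 10)
  P_I1 <- strrep("AAG", 7);  P_I2 <- strrep("TTC", 7)
  ct <- fake_catalog(c(P_O1, P_O2, P_I1, P_I2),
                     data.frame(cand = 1:4, gene = 1L,
                                start = c(0L, 200L, 50L, 129L),
                                strand = c("+", "-", "+", "-")))
  genes <- gene_set(c(g1 = rand_oligo(250)))
  base <- primertile:::new_design(
    list(rbind(c(0L, 220L, 1L, 2L), c(50L, 150L, 3L, 4L))),
    ct, genes, primer_config())
  expect_identical(remove_nested_pairs(base, prob = 0)$amps, base$amps)
  gone <- remove_nested_pairs(base, prob = 1)
  expect_identical(nrow(gone$amps[[1]]), 1L)
  expect_identical(gone$amps[[1]][1, 2], 220L)
  removed <- vapply(1:2000, function(i)
    nrow(remove_nested_pairs(base, prob = 0.5)$amps[[1]]) == 1, logical(1))
  expect_lt(abs(mean(removed) - 0.5), 0.05)
})

test_that("optimization: monotone best trace, reproducibility, valid output", {
  res <- run_optimization(fx_small$genes, cat_small, cfg_small)
  expect_true(all(diff(res$trace$best_cost) <= 0))
  expect_equal(res$best_cost, min(res$trace$best_cost))
  expect_true(validate_design(res$design)$ok)
  expect_true(all(res$trace$method %in% 1:3))
  # accepted implies the next current cost equals the proposal cost
  acc <- which(res$trace$accepted[-nrow(res$trace)])
  expect_true(all(res$trace$C[acc + 1] == res$trace$C_prop[acc]))
  res2 <- run_optimization(fx_small$genes, cat_small, cfg_small)
  expect_identical(res$trace, res2$trace)
})

test_that("the exhaustive oracle bounds and matches small-instance runs", {
  inst <- make_oracle_instance(61)
  orc <- inst$oracle
  expect_gte(orc$n_feasible, 1)
  # every optimizer run is bounded below by the oracle optimum
  costs <- vapply(1:5, function(s) {
    cfg <- inst$cfg; cfg$rng_seed <- 100L + s
    run_optimization(inst$genes, inst$catalog, cfg, trace = FALSE)$best_cost
  }, numeric(1))
  expect_true(all(costs >= orc$cost))
  expect_true(any(costs == orc$cost))
})

test_that("oracle hand cases: single feasible amplicon, and shared-primer preference", {
  # gene with exactly one feasible amplicon
  set.seed(8)
  P_F <- paste0(strrep("A", 10), strrep("G", 10))
  P_R <- strrep("TC", 10)
  ct1 <- fake_catalog(c(P_F, P_R),
                      data.frame(cand = 1:2, gene = 1L,
                                 start = c(0L, 80L), strand = c("+", "-")))
  genes <- gene_set(c(g1 = rand_oligo(120)))
  cfg <- primer_config()
  orc <- oracle_optimal_cost(genes, ct1, cfg)
  expect_identical(orc$cost, 40L)
  expect_identical(orc$n_amplicons, 1L)
  # two genes; the reverse primer is shared between their only amplicons,
  # so the optimum pays for three primers, not four
  P_F2 <- paste0(strrep("T", 10), strrep("G", 10))
  ct2 <- fake_catalog(
    c(P_F, P_R, P_F2),
    data.frame(cand = c(1L, 2L, 3L, 2L), gene = c(1L, 1L, 2L, 2L),
               start = c(0L, 80L, 0L, 80L), strand = c("+", "-", "+", "-")))
  genes2 <- gene_set(c(g1 = rand_oligo(120), g2 = rand_oligo(120)))
  orc2 <- oracle_optimal_cost(genes2, ct2, cfg)
  expect_identical(orc2$cost, 60L)
  expect_identical(orc2$n_amplicons, 2L)
})

test_that("early stopping halts a stalled chain after the early window", {
  cfg <- cfg_small
  cfg$early_proportion <- 0.1
  cfg$cost_tolerance <- 1e9          # any improvement counts as stalled
  res <- run_optimization(fx_small$genes, cat_small, cfg)
  expect_lt(res$iterations_run, cfg$n_iterations)
})

test_that("interim checkpoints are written and can seed a restart", {
  tmp <- withr::local_tempdir()
  cfg <- cfg_small
  cfg$n_iterations <- 1000L
  cfg$save_interim <- TRUE
  cfg$output_path <- file.path(tmp, "run.out")
  res <- run_optimization(fx_small$genes, cat_small, cfg)
  ckpt <- paste0(cfg$output_path, ".checkpoint.tsv")
  expect_true(file.exists(ckpt))
  d <- primertile:::.read_design_tsv(ckpt, cat_small, fx_small$genes, cfg)
  expect_true(validate_design(d)$ok)
  # a restarted run starts from the checkpointed design
  cfg2 <- cfg
  cfg2$restart <- TRUE
  cfg2$save_interim <- FALSE
  cfg2$n_iterations <- 50L
  res2 <- run_optimization(fx_small$genes, cat_small, cfg2)
  expect_lte(res2$best_cost, primertile:::.objective(d$amps, cat_small))
})
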