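# Metropolis-Hastings optimization of the amplicon tiling: initial design
# construction, the three greedy proposal generators, iteration-third method
# scheduling, uphill acceptance with heating, nested-pair slack removal, the
# full sampling loop, and a brute-force optimum oracle for small instances.

## ---- lookup tables ---------------------------------------------------------
# Per gene: sorted forward starts / reverse ends with the best-weighted
# candidate precomputed at each locus (selection at a locus is deterministic
# given the catalogue weights), plus the full per-locus tables for
# repositioning and reuse-swapping; a memo environment caches pairwise
# forward/reverse dimer compatibility.

.build_lookup <- function(catalog, genes, cfg) {
  per_gene <- vector("list", length(genes$id))
  for (gi in seq_along(genes$id)) {
    s <- catalog$sites[catalog$sites$gene == gi, , drop = FALSE]
    fw <- s[s$strand == "+", , drop = FALSE]
    fw$rank <- catalog$rank[fw$cand]
    fw <- fw[order(fw$start, fw$rank), , drop = FALSE]
    fbest <- fw[!duplicated(fw$start), , drop = FALSE]
    rv <- s[s$strand == "-", , drop = FALSE]
    rv$end <- rv$start + catalog$length[rv$cand]
    rv$rank <- catalog$rank[rv$cand]
    rv <- rv[order(rv$end, rv$rank), , drop = FALSE]
    rbest <- rv[!duplicated(rv$end), , drop = FALSE]
    n <- genes$length[gi]
    # dense position -> locus-index tables (O(1) replacements for sorted
    # search inside the sampling loop); index by position + 1, 0..n
    f_ge <- findInterval(0:n - 0.5, fbest$start) + 1L
    f_le <- findInterval(0:n, fbest$start)
    r_ge <- findInterval(0:n - 0.5, rbest$end) + 1L
    r_le <- findInterval(0:n, rbest$end)
    per_gene[[gi]] <- list(
      fs = fbest$start, fc = fbest$cand,       # best fwd per start
      re = rbest$end, rc = rbest$cand,         # best rev per end
      f_ge = f_ge, f_le = f_le, r_ge = r_ge, r_le = r_le,
      fall = fw[, c("start", "cand")], rall = rv[, c("end", "cand")])
  }
  list(per_gene = per_gene, catalog = catalog, cfg = cfg,
       glen = genes$length, genes = genes,
       pair_memo = new.env(hash = TRUE, parent = emptyenv()),
       dimer_cache = new.env(hash = TRUE, parent = emptyenv()))
}

# per-candidate dimer profile, built on first touch: concrete expansions,
# each with its reverse-complemented 3' seed and the 8-mer set of its
# reverse complement (for the contiguous-duplex rule)
.dimer_profile <- function(lk, id) {
  key <- as.character(id)
  prof <- lk$dimer_cache[[key]]
  if (!is.null(prof)) return(prof)
  E <- expand_degenerate(lk$catalog$seq[id])
  L <- nchar(E[1L])
  rc <- revcomp(E)
  prof <- list(
    E = E,
    rc3 = substr(rc, 1L, 5L),                         # revcomp of 3' 5-mer
    k8 = lapply(E, function(s) substring(s, 1:(L - 7L), 8:L)),
    k8rc = lapply(rc, function(s) substring(s, 1:(L - 7L), 8:L)))
  assign(key, prof, envir = lk$dimer_cache)
  prof
}

# forward/reverse pair admissible: different sequences, no cross-dimer
# (same thresholds as check_dimer: 3' 5-mer seed or >= 8 bp duplex)
.pair_ok <- function(lk, f, r) {
  key <- paste0(f, ".", r)
  hit <- lk$pair_memo[[key]]
  if (!is.null(hit)) return(hit)
  ok <- lk$catalog$seq[f] != lk$catalog$seq[r]
  if (ok) {
    pf <- .dimer_profile(lk, f); pr <- .dimer_profile(lk, r)
    for (i in seq_along(pf$E)) {
      for (j in seq_along(pr$E)) {
        if (grepl(pf$rc3[i], pr$E[j], fixed = TRUE) ||
            grepl(pr$rc3[j], pf$E[i], fixed = TRUE) ||
            any(pf$k8[[i]] %in% pr$k8rc[[j]])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
  }
  assign(key, ok, envir = lk$pair_memo)
  ok
}

.first_ge <- function(vec, x) findInterval(x - 1L, vec) + 1L  # sorted ints
.last_le <- function(vec, x) findInterval(x, vec)

## ---- tiling ----------------------------------------------------------------
# Tile one gene with amplicons starting from a random seed position:
# forward from the seed to the gene end, then leftwards to cover the region
# before the seed. Amplicon sizes are drawn uniformly from
# [amplicon_min, amplicon_max]; at each locus the best-weighted primer is
# taken; consecutive amplicons overlap by initial_overlap bp.
.tile_gene <- function(lk, gi, seed, used_pairs) {
  cfg <- lk$cfg
  pg <- lk$per_gene[[gi]]
  n <- lk$glen[gi]
  out <- matrix(integer(0), ncol = 4L)
  if (length(pg$fs) == 0L || length(pg$re) == 0L) return(out)
  amin <- cfg$amplicon_min; amax <- cfg$amplicon_max
  lens <- amin - 1L + sample.int(amax - amin + 1L, 32L, replace = TRUE)
  li <- 0L
  draw_len <- function() {
    li <<- li + 1L
    if (li > 32L) { lens <<- amin - 1L +
      sample.int(amax - amin + 1L, 32L, replace = TRUE); li <<- 1L }
    lens[li]
  }
  # nearest-first search over a sorted locus window: try the locus closest
  # to `target` first, expanding outwards, returning the first admissible
  try_window <- function(pos, cand, jlo, jhi, hi, fixed_id, fwd_side, target) {
    hi <- max(hi, jlo)
    lo <- hi - 1L
    while (lo >= jlo || hi <= jhi) {
      j <- if (hi > jhi) lo
           else if (lo < jlo) hi
           else if (target - pos[lo] <= pos[hi] - target) lo else hi
      key <- if (fwd_side) paste0(cand[j], ".", fixed_id)
             else paste0(fixed_id, ".", cand[j])
      ok <- is.null(used_pairs[[key]]) &&
        (if (fwd_side) .pair_ok(lk, cand[j], fixed_id)
         else .pair_ok(lk, fixed_id, cand[j]))
      if (ok) { used_pairs[[key]] <- TRUE; return(j) }
      if (j == lo) lo <- lo - 1L else hi <- hi + 1L
    }
    0L
  }
  rows <- list()
  s <- seed
  repeat {
    i <- pg$f_ge[s + 1L]
    if (i > length(pg$fs)) break
    f <- pg$fs[i]; fcand <- pg$fc[i]
    if (f + amin > n) break
    e0 <- min(f + draw_len(), n)
    jlo <- pg$r_ge[f + amin + 1L]
    jhi <- pg$r_le[min(f + amax, n) + 1L]
    j <- if (jlo <= jhi)
      try_window(pg$re, pg$rc, jlo, jhi, pg$r_le[e0 + 1L] + 1L, fcand,
                 fwd_side = FALSE, target = e0)
    else 0L
    if (j > 0L) {
      rows[[length(rows) + 1L]] <- c(f, pg$re[j], fcand, pg$rc[j])
      s <- max(pg$re[j] - cfg$initial_overlap, f + 1L)
    } else s <- f + 1L
  }
  # leftward fill before the first amplicon
  b_e <- if (length(rows)) rows[[1L]][1L] + cfg$initial_overlap else min(seed, n)
  repeat {
    if (b_e < amin) break
    i <- pg$r_le[b_e + 1L]
    if (i < 1L) break
    e <- pg$re[i]; rcand <- pg$rc[i]
    if (e < amin) break
    f0 <- max(e - draw_len(), 0L)
    jlo <- pg$f_ge[max(e - amax, 0L) + 1L]
    jhi <- pg$f_le[e - amin + 1L]
    j <- if (jlo <= jhi)
      try_window(pg$fs, pg$fc, jlo, jhi, pg$f_le[f0 + 1L] + 1L, rcand,
                 fwd_side = TRUE, target = f0)
    else 0L
    if (j > 0L) {
      rows <- c(list(c(pg$fs[j], e, pg$fc[j], rcand)), rows)
      b_e <- min(pg$fs[j] + cfg$initial_overlap, e - 1L)
    } else b_e <- e - 1L
  }
  if (length(rows) == 0L) {
    # a seed falling in a locus desert can strand a coverable gene; retry
    # once from the gene start, which visits every forward locus in order
    if (seed > 0L) return(.tile_gene(lk, gi, 0L, used_pairs))
    return(out)
  }
  m <- do.call(rbind, rows)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

.seed_pairs_env <- function(amps, skip_gene = 0L) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (gi in seq_along(amps)) {
    if (gi == skip_gene) next
    m <- amps[[gi]]
    if (nrow(m) == 0L) next
    for (key in paste0(m[, 3L], ".", m[, 4L])) env[[key]] <- TRUE
  }
  env
}

.build_amps <- function(lk) {
  cfg <- lk$cfg
  amps <- vector("list", length(lk$glen))
  used <- new.env(hash = TRUE, parent = emptyenv())
  for (gi in sample.int(length(lk$glen))) {   # genes in random order
    n <- lk$glen[gi]
    seed <- sample.int(n, 1L) - 1L
    amps[[gi]] <- .tile_gene(lk, gi, seed, used)
  }
  if (cfg$remove_nonreusable) amps <- .swap_to_reusable(lk, amps)
  amps
}

# replace design-unique primers by already-used alternatives at the same
# locus where an admissible one exists
.swap_to_reusable <- function(lk, amps) {
  uses <- table(.design_ids(amps))
  used_of <- function(id) {
    u <- uses[as.character(id)]
    if (is.na(u)) 0L else as.integer(u)
  }
  for (gi in seq_along(amps)) {
    m <- amps[[gi]]
    pg <- lk$per_gene[[gi]]
    for (k in seq_len(nrow(m))) {
      for (side in 3:4) {
        id <- m[k, side]
        if (used_of(id) > 1L) next
        alt <- if (side == 3L) pg$fall$cand[pg$fall$start == m[k, 1L]]
               else pg$rall$cand[pg$rall$end == m[k, 2L]]
        alt <- setdiff(alt, id)
        alt <- alt[vapply(alt, used_of, integer(1L)) >= 1L]
        other <- m[k, if (side == 3L) 4L else 3L]
        for (a in alt) {
          f <- if (side == 3L) a else other
          r <- if (side == 3L) other else a
          if (.pair_ok(lk, f, r)) { m[k, side] <- a; break }
        }
      }
    }
    amps[[gi]] <- m
  }
  amps
}

## ---- exported proposal operations -----------------------------------------

#' Build an initial design
#'
#' Covers the gene set by visiting genes in random order and tiling each
#' from a uniformly random seed position; amplicon sizes are drawn
#' uniformly from `[amplicon_min, amplicon_max]`, the best-weighted
#' available primer is chosen at each locus, and consecutive amplicons
#' overlap by `initial_overlap` bp (slack for the later optimization). With
#' `remove_nonreusable`, single-use primers are swapped for already-used
#' alternatives at the same locus where one exists. Genes with no feasible
#' amplicon remain uncovered.
#'
#' @param genes A [gene_set()].
#' @param catalog A `primer_catalog` from [prepare_candidates()].
#' @param cfg A [primer_config()].
#' @return A `primer_design`.
#' @export
build_initial_design <- function(genes, catalog, cfg) {
  lk <- .build_lookup(catalog, genes, cfg)
  new_design(.build_amps(lk), catalog, genes, cfg, lookup = lk)
}

.design_lookup <- function(d) {
  if (is.null(d$lookup)) d$lookup <- .build_lookup(d$catalog, d$genes, d$cfg)
  d$lookup
}

#' Proposal 1: global re-seeding
#'
#' A fresh complete alternative design built as in
#' [build_initial_design()]; primer loci are effectively swapped, with more
#' reusable primers preferred at every locus through the weight order.
#'
#' @param d Current `primer_design`.
#' @return A new `primer_design`.
#' @export
propose_method1_global <- function(d) {
  lk <- .design_lookup(d)
  new_design(.build_amps(lk), d$catalog, d$genes, d$cfg, lookup = lk)
}

#' Proposal 2: per-gene refinement
#'
#' Re-seeds one uniformly chosen gene, keeping the accepted arrangement of
#' every other gene.
#'
#' @inheritParams propose_method1_global
#' @return A new `primer_design` differing from `d` on at most one gene.
#' @export
propose_method2_gene <- function(d) {
  lk <- .design_lookup(d)
  amps <- d$amps
  gi <- sample.int(length(amps), 1L)
  used <- .seed_pairs_env(amps, skip_gene = gi)
  amps[[gi]] <- .tile_gene(lk, gi, sample.int(lk$glen[gi], 1L) - 1L, used)
  new_design(amps, d$catalog, d$genes, d$cfg, lookup = lk)
}

#' Proposal 3: single-primer repositioning
#'
#' Moves one uniformly chosen primer locus (forward start or reverse end of
#' one amplicon) to a random alternative binding site keeping the amplicon
#' within `[amplicon_min, amplicon_max]` and the design valid; if no
#' admissible alternative exists the proposal is the unchanged design.
#'
#' @inheritParams propose_method1_global
#' @return A new `primer_design`.
#' @export
propose_method3_reposition <- function(d) {
  lk <- .design_lookup(d)
  amps <- .reposition(lk, d$amps)
  new_design(amps, d$catalog, d$genes, d$cfg, lookup = lk)
}

.reposition <- function(lk, amps) {
  cfg <- lk$cfg
  counts <- vapply(amps, nrow, integer(1L))
  if (sum(counts) == 0L) return(amps)
  pick <- sample.int(sum(counts), 1L)
  gi <- which(cumsum(counts) >= pick)[1L]
  k <- pick - c(0L, cumsum(counts))[gi]
  m <- amps[[gi]]
  pg <- lk$per_gene[[gi]]
  n <- lk$glen[gi]
  side <- sample(c(3L, 4L), 1L)
  s <- m[k, 1L]; e <- m[k, 2L]
  pairs_env <- .seed_pairs_env(amps)          # all current pairs
  # drop this amplicon's own pair so it can re-form
  rm(list = paste0(m[k, 3L], ".", m[k, 4L]), envir = pairs_env)
  if (side == 3L) {
    jlo <- pg$f_ge[max(e - cfg$amplicon_max, 0L) + 1L]
    jhi <- pg$f_le[e - cfg$amplicon_min + 1L]
    cand_idx <- if (jlo <= jhi) setdiff(jlo:jhi, which(pg$fs == s)) else integer(0)
    for (j in cand_idx[sample.int(length(cand_idx))]) {
      f <- pg$fc[j]
      key <- paste0(f, ".", m[k, 4L])
      if (!is.null(pairs_env[[key]])) next
      if (!.pair_ok(lk, f, m[k, 4L])) next
      m[k, 1L] <- pg$fs[j]; m[k, 3L] <- f
      break
    }
  } else {
    jlo <- pg$r_ge[s + cfg$amplicon_min + 1L]
    jhi <- pg$r_le[min(s + cfg$amplicon_max, n) + 1L]
    cand_idx <- if (jlo <= jhi) setdiff(jlo:jhi, which(pg$re == e)) else integer(0)
    for (j in cand_idx[sample.int(length(cand_idx))]) {
      r <- pg$rc[j]
      key <- paste0(m[k, 3L], ".", r)
      if (!is.null(pairs_env[[key]])) next
      if (!.pair_ok(lk, m[k, 3L], r)) next
      m[k, 2L] <- pg$re[j]; m[k, 4L] <- r
      break
    }
  }
  amps[[gi]] <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  amps
}

#' Choose the greedy proposal method for an iteration
#'
#' The three proposal generators are applied progressively: with
#' `weight_greedy` on, the method matching the current third of the run
#' (global re-seeding in the first third, per-gene refinement in the
#' second, repositioning in the last) is drawn with probability 0.8 and the
#' other two with 0.1 each, so all three remain reachable at any time; with
#' `weight_greedy` off all three are drawn uniformly.
#'
#' @param iteration 0-based iteration index (below `cfg$n_iterations`).
#' @param cfg A [primer_config()].
#' @return Integer method id 1, 2 or 3.
#' @export
choose_method <- function(iteration, cfg) {
  stopifnot(iteration >= 0L, iteration < cfg$n_iterations)
  if (!cfg$weight_greedy) return(sample.int(3L, 1L))
  third <- min(floor(3 * iteration / cfg$n_iterations) + 1L, 3L)
  p <- rep(0.1, 3L); p[third] <- 0.8
  sample.int(3L, 1L, prob = p)
}

#' Metropolis acceptance rule
#'
#' For proposal cost `C'` against current cost `C`, with `deltaS = C' - C`:
#' a cost-lowering proposal (`deltaS < 0`) is always accepted; otherwise
#' acceptance has probability `min(1, exp(-deltaS * H))` (Boltzmann rule;
#' `deltaS = 0` is accepted with probability 1). Under
#' `mode = "fraction"` an uphill proposal is instead accepted with fixed
#' probability `H`. Vectorized over `C`/`Cp`.
#'
#' @param C Current cost(s).
#' @param Cp Proposal cost(s).
#' @param H Heating (>= 0; larger H rejects uphill moves more strongly).
#' @param mode `"boltzmann"` (default) or `"fraction"`.
#' @return Logical vector of acceptance decisions.
#' @export
metropolis_accept <- function(C, Cp, H, mode = c("boltzmann", "fraction")) {
  mode <- match.arg(mode)
  stopifnot(H >= 0)
  dS <- Cp - C
  p <- if (mode == "boltzmann") pmin(1, exp(-dS * H))
       else ifelse(dS < 0, 1, H)
  stats::runif(length(dS)) < p
}

#' Remove nested amplicon pairs
#'
#' Slack built into the initial design (overlapping amplicons) can evolve
#' until one amplicon lies entirely inside a neighbour; each such nested
#' amplicon is deleted independently with probability
#' `prob_remove_redundant`, controlling the rate at which slack leaves the
#' design.
#'
#' @param d A `primer_design`.
#' @param prob Removal probability in `[0, 1]` (defaults to the
#'   configuration's `prob_remove_redundant`).
#' @return A `primer_design` without (some of) its nested amplicons.
#' @export
remove_nested_pairs <- function(d, prob = d$cfg$prob_remove_redundant) {
  stopifnot(inherits(d, "primer_design"))
  d$amps <- .remove_nested(d$amps, prob)
  d
}

.remove_nested <- function(amps, prob) {
  if (prob <= 0) return(amps)
  for (gi in seq_along(amps)) {
    m <- amps[[gi]]
    if (nrow(m) < 2L) next
    nested <- vapply(seq_len(nrow(m)), function(k)
      any(m[, 1L] <= m[k, 1L] & m[k, 2L] <= m[, 2L] &
            seq_len(nrow(m)) != k &
            (m[, 1L] != m[k, 1L] | m[, 2L] != m[k, 2L])), logical(1L))
    drop <- nested & stats::runif(nrow(m)) < prob
    if (any(drop)) amps[[gi]] <- m[!drop, , drop = FALSE]
  }
  amps
}

## ---- the sampling loop -----------------------------------------------------

#' Run the Metropolis-Hastings cost optimization
#'
#' `cfg$n_iterations` iterations of method choice, greedy proposal,
#' Metropolis acceptance with heating, and nested-pair removal. The
#' objective is the design cost over distinct primers (every use charged
#' separately when `cfg$reuse_costing` is off); coverage is reported but
#' not optimized. Fully reproducible from `cfg$rng_seed`; when
#' `cfg$save_interim` is set, the current design is checkpointed every 1000
#' iterations, and with `cfg$restart` the checkpoint seeds the initial
#' design. Optional early stopping: with `early_proportion > 0`, the run
#' stops once the best cost has improved by no more than `cost_tolerance`
#' over a sliding window of `n_iterations * early_proportion` iterations.
#'
#' @param genes A [gene_set()].
#' @param catalog A `primer_catalog` for one target melting temperature.
#' @param cfg A [primer_config()].
#' @param trace Keep the per-iteration trace (default `TRUE`).
#' @return List with `design` (best-cost `primer_design` ever seen),
#'   `best_cost`, `trace` (data frame: `iteration`, `method`, `C`,
#'   `C_prop`, `delta`, `accepted`, `best_cost`, `coverage`) and
#'   `iterations_run`.
#' @export
run_optimization <- function(genes, catalog, cfg, trace = TRUE) {
  stopifnot(inherits(genes, "gene_set"), inherits(catalog, "primer_catalog"))
  if (!is.na(cfg$rng_seed)) set.seed(cfg$rng_seed)
  lk <- .build_lookup(catalog, genes, cfg)
  obj <- function(amps) .objective(amps, catalog, cfg$reuse_costing)
  cur <- NULL
  if (cfg$restart) {
    ckpt <- paste0(cfg$output_path, ".checkpoint.tsv")
    if (file.exists(ckpt)) cur <- .read_design_tsv(ckpt, catalog, genes, cfg)$amps
  }
  if (is.null(cur)) cur <- .build_amps(lk)
  Ccur <- obj(cur)
  best <- cur; bestC <- Ccur
  cov_cur <- NA_integer_
  nit <- cfg$n_iterations
  tr_method <- integer(nit); tr_C <- tr_Cp <- tr_best <- tr_cov <- numeric(nit)
  tr_acc <- logical(nit)
  window <- if (cfg$early_proportion > 0)
    max(1L, ceiling(nit * cfg$early_proportion)) else NA_integer_
  best_hist <- numeric(nit)
  it_done <- 0L
  for (it in 0:(nit - 1L)) {
    m <- choose_method(it, cfg)
    prop <- switch(m, .build_amps(lk), {
      gi <- sample.int(length(cur), 1L)
      used <- .seed_pairs_env(cur, skip_gene = gi)
      tmp <- cur
      tmp[[gi]] <- .tile_gene(lk, gi, sample.int(lk$glen[gi], 1L) - 1L, used)
      tmp
    }, .reposition(lk, cur))
    Cp <- obj(prop)
    dS <- Cp - Ccur
    acc <- if (cfg$heating_mode == "boltzmann")
      dS < 0 || stats::runif(1L) < exp(-dS * cfg$heating)
    else dS < 0 || stats::runif(1L) < cfg$heating
    tr_C[it + 1L] <- Ccur; tr_Cp[it + 1L] <- Cp
    tr_method[it + 1L] <- m; tr_acc[it + 1L] <- acc
    if (acc) { cur <- prop; Ccur <- Cp; cov_cur <- NA_integer_ }
    if (cfg$prob_remove_redundant > 0) {
      cur <- .remove_nested(cur, cfg$prob_remove_redundant)
      Ccur <- obj(cur); cov_cur <- NA_integer_
    }
    if (Ccur < bestC) { best <- cur; bestC <- Ccur }
    tr_best[it + 1L] <- bestC
    if (is.na(cov_cur))
      cov_cur <- sum(vapply(cur, .coverage_one, integer(1L)))
    tr_cov[it + 1L] <- cov_cur
    best_hist[it + 1L] <- bestC
    it_done <- it + 1L
    if (cfg$save_interim && (it + 1L) %% 1000L == 0L)
      .write_design_tsv(new_design(cur, catalog, genes, cfg),
                        paste0(cfg$output_path, ".checkpoint.tsv"))
    if (!is.na(window) && it + 1L > window &&
        best_hist[it + 1L - window] - bestC <= cfg$cost_tolerance) break
    if (cfg$verbose && (it + 1L) %% 1000L == 0L)
      message("iteration ", it + 1L, ": current ", Ccur, " best ", bestC)
  }
  keep <- seq_len(it_done)
  out <- list(design = new_design(best, catalog, genes, cfg, lookup = lk),
              best_cost = bestC, iterations_run = it_done)
  if (trace)
    out$trace <- data.frame(
      iteration = keep - 1L, method = tr_method[keep], C = tr_C[keep],
      C_prop = tr_Cp[keep], delta = tr_Cp[keep] - tr_C[keep],
      accepted = tr_acc[keep], best_cost = tr_best[keep],
      coverage = tr_cov[keep])
  out
}

## ---- exhaustive oracle -----------------------------------------------------

#' Brute-force optimum for small instances
#'
#' Enumerates every valid tiling (subsets of all feasible amplicons that
#' are pairwise non-nested with unique, dimer-free primer pairs), restricts
#' to those achieving the maximal attainable coverage, and returns the
#' minimum distinct-primer cost among them. Refuses instances whose subset
#' space exceeds about a million tilings. A test oracle: the optimizer can
#' never report a best cost below this bound on oracle-sized instances.
#'
#' @param genes A [gene_set()].
#' @param catalog A `primer_catalog`.
#' @param cfg A [primer_config()].
#' @return List with `cost` (nucleotides), `coverage` (bp) and
#'   `n_amplicons` of the optimum, plus `n_feasible` amplicons enumerated.
#' @export
oracle_optimal_cost <- function(genes, catalog, cfg) {
  lk <- .build_lookup(catalog, genes, cfg)
  fs <- catalog$sites
  fwd <- fs[fs$strand == "+", , drop = FALSE]
  rev <- fs[fs$strand == "-", , drop = FALSE]
  rev$end <- rev$start + catalog$length[rev$cand]
  amp <- list()
  for (gi in seq_along(genes$id)) {
    fg <- fwd[fwd$gene == gi, , drop = FALSE]
    rg <- rev[rev$gene == gi, , drop = FALSE]
    for (a in seq_len(nrow(fg))) for (b in seq_len(nrow(rg))) {
      len <- rg$end[b] - fg$start[a]
      if (len < cfg$amplicon_min || len > cfg$amplicon_max) next
      if (!.pair_ok(lk, fg$cand[a], rg$cand[b])) next
      amp[[length(amp) + 1L]] <- c(gi, fg$start[a], rg$end[b],
                                   fg$cand[a], rg$cand[b])
    }
  }
  m <- length(amp)
  if (m == 0L) return(list(cost = 0L, coverage = 0L, n_amplicons = 0L,
                           n_feasible = 0L))
  if (2^m > 1e6)
    stop("oracle_optimal_cost: search space too large (", m, " amplicons)")
  A <- do.call(rbind, amp)
  nested <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
    i != j && A[i, 1L] == A[j, 1L] &&
      A[j, 2L] <= A[i, 2L] && A[i, 3L] <= A[j, 3L]))
  pkey <- paste0(A[, 4L], ".", A[, 5L])
  best_cov <- -1L; best_cost <- Inf; best_n <- 0L
  # depth-first enumeration with incremental validity
  recurse <- function(i, sel) {
    if (i > m) {
      if (length(sel) == 0L) return(invisible(NULL))
      cov <- 0L
      for (gi in unique(A[sel, 1L])) {
        mm <- A[sel[A[sel, 1L] == gi], 2:3, drop = FALSE]
        cov <- cov + .coverage_one(cbind(mm, 0L, 0L))
      }
      cost <- sum(catalog$length[unique(as.integer(A[sel, 4:5]))])
      if (cov > best_cov || (cov == best_cov && cost < best_cost)) {
        if (cov > best_cov) { best_cov <<- cov; best_cost <<- Inf }
        if (cost < best_cost) { best_cost <<- cost; best_n <<- length(sel) }
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, sel)                       # without amplicon i
    ok <- !any(nested[i, sel] | nested[sel, i]) &&
      !pkey[i] %in% pkey[sel]
    if (ok) recurse(i + 1L, c(sel, i))         # with amplicon i
    invisible(NULL)
  }
  recurse(1L, integer(0))
  list(cost = as.integer(best_cost), coverage = best_cov,
       n_amplicons = best_n, n_feasible = m)
}

## ---- temperature sweep -----------------------------------------------------

#' Design primers across the configured melting-temperature range
#'
#' For each integer melting temperature in `[tm_min, tm_max]`, runs the
#' full preparation pipeline and the MCMC optimization, collecting cost,
#' coverage and the reuse histogram per temperature.
#'
#' @param genes A [gene_set()].
#' @param cfg A [primer_config()].
#' @param background Optional background sequences for redundancy bounds.
#' @param trace Keep per-iteration traces (default `FALSE`).
#' @return An object of class `tm_sweep`: list with `summary` (data frame:
#'   `tm`, `n_candidates`, `cost`, `coverage`, `pct_coverage`,
#'   `cost_per_base`, `n_distinct_primers`, `n_reused_primers`),
#'   `designs`, `histograms`, `traces` (if requested) and `cfg`.
#' @export
run_tm_sweep <- function(genes, cfg, background = NULL, trace = FALSE) {
  stopifnot(cfg$tm_min <= cfg$tm_max)
  tms <- cfg$tm_min:cfg$tm_max
  total_len <- sum(genes$length)
  designs <- hists <- traces <- vector("list", length(tms))
  rows <- vector("list", length(tms))
  for (i in seq_along(tms)) {
    cat_i <- prepare_candidates(genes, tms[i], cfg, background)
    if (length(cat_i$seq) == 0L) {
      rows[[i]] <- data.frame(tm = tms[i], n_candidates = 0L,
                              cost = NA_integer_, coverage = NA_integer_,
                              pct_coverage = NA_real_,
                              cost_per_base = NA_real_,
                              n_distinct_primers = 0L, n_reused_primers = 0L)
      designs[[i]] <- NULL
      hists[[i]] <- list(histogram = integer(0), n_distinct = 0L,
                         no_reuse_total = 0L, reduction_pct = 0)
      next
    }
    res <- run_optimization(genes, cat_i, cfg, trace = trace)
    d <- res$design
    cost <- design_cost(d); cov <- design_coverage(d)
    h <- redundancy_histogram(d)
    rows[[i]] <- data.frame(
      tm = tms[i], n_candidates = length(cat_i$seq), cost = cost,
      coverage = cov,
      pct_coverage = round(100 * cov / total_len, 2L),
      cost_per_base = if (cov > 0L) cost_per_covered_base(cost, cov) else NA_real_,
      n_distinct_primers = h$n_distinct,
      n_reused_primers = sum(h$histogram[as.integer(names(h$histogram)) >= 2L]))
    designs[[i]] <- d
    hists[[i]] <- h
    if (trace) traces[[i]] <- res$trace
  }
  structure(list(summary = do.call(rbind, rows), designs = designs,
                 histograms = hists, traces = if (trace) traces,
                 cfg = cfg, genes = genes),
            class = "tm_sweep")
}

#' @export
print.tm_sweep <- function(x, ...) {
  cat("tm_sweep over", nrow(x$summary), "melting temperature(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

## ---- checkpoint serialization ---------------------------------------------

.write_design_tsv <- function(d, path) {
  rows <- list()
  for (gi in seq_along(d$amps)) {
    m <- d$amps[[gi]]
    for (k in seq_len(nrow(m)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = d$genes$id[gi], start = m[k, 1L], end = m[k, 2L],
        fwd = d$catalog$seq[m[k, 3L]], rev = d$catalog$seq[m[k, 4L]],
        stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               fwd = character(0), rev = character(0))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_design_tsv <- function(path, catalog, genes, cfg) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  amps <- rep(list(matrix(integer(0), ncol = 4L)), length(genes$id))
  for (gi in seq_along(genes$id)) {
    sub <- tab[tab$gene == genes$id[gi], , drop = FALSE]
    if (nrow(sub) == 0L) next
    f <- match(sub$fwd, catalog$seq); r <- match(sub$rev, catalog$seq)
    ok <- !is.na(f) & !is.na(r)
    if (!any(ok)) next
    amps[[gi]] <- cbind(as.integer(sub$start[ok]), as.integer(sub$end[ok]),
                        f[ok], r[ok])
  }
  new_design(amps, catalog, genes, cfg)
}
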