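# Plain-text results file and cross-run summary statistics.

#' Write the results file for a temperature sweep
#'
#' One block per melting temperature: a header (Tm, seed, iterations), the
#' primer table (sequence, length, degeneracy, reuse level, binding loci;
#' degenerate primers flagged), then the covered bases, the final cost in
#' nucleotides and the cost per covered base. Ordering is deterministic:
#' genes in input order, primers by weight. Re-running with the same seed
#' reproduces the file byte for byte.
#'
#' @param sweep A `tm_sweep` from [run_tm_sweep()].
#' @param path Output path (defaults to the configuration's `output_path`).
#' @return Invisibly, the path written.
#' @export
write_output <- function(sweep, path = sweep$cfg$output_path) {
  stopifnot(inherits(sweep, "tm_sweep"))
  cfg <- sweep$cfg
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# primer design results")
  for (i in seq_len(nrow(sweep$summary))) {
    row <- sweep$summary[i, ]
    w("")
    w("== Tm ", row$tm, " C | seed ",
      ifelse(is.na(cfg$rng_seed), "none", cfg$rng_seed),
      " | iterations ", cfg$n_iterations, " ==")
    d <- sweep$designs[[i]]
    if (is.null(d) || length(.design_ids(d$amps)) == 0L) {
      w("no primers designed")
      w("covered bases\t0")
      w("final cost (nucleotides)\t0")
      next
    }
    ids <- .design_ids(d$amps)
    uses <- table(ids)
    uid <- as.integer(names(uses))
    ord <- order(d$catalog$rank[uid])
    w("primer\tlength\tdegeneracy\treuse\tloci")
    for (u in uid[ord]) {
      s <- d$catalog$sites[d$catalog$sites$cand == u, , drop = FALSE]
      loci <- paste(sprintf("%s:%d:%s", d$genes$id[s$gene], s$start,
                            s$strand), collapse = ",")
      flag <- if (d$catalog$n_degenerate[u] > 0L) " [degenerate]" else ""
      w(d$catalog$seq[u], flag, "\t", d$catalog$length[u], "\t",
        d$catalog$n_degenerate[u], "\t", uses[as.character(u)], "\t", loci)
    }
    w("covered bases\t", row$coverage)
    w("final cost (nucleotides)\t", row$cost)
    w("cost per covered base\t", format(row$cost_per_base, nsmall = 2L))
  }
  invisible(path)
}

#' Parse a results file back into its metrics
#'
#' Round-trip companion of [write_output()]: recovers per-temperature cost,
#' coverage and primer count.
#'
#' @param path Path to a results file.
#' @return Data frame with `tm`, `cost`, `coverage`, `n_primers`.
#' @export
read_output <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- grep("^== Tm ", lines)
  out <- lapply(seq_along(blocks), function(i) {
    from <- blocks[i]
    to <- if (i < length(blocks)) blocks[i + 1L] - 1L else length(lines)
    chunk <- lines[from:to]
    tm <- as.integer(sub("^== Tm (\\d+) C.*$", "\\1", chunk[1L]))
    getv <- function(key) {
      ln <- grep(paste0("^", key, "\t"), chunk, value = TRUE)
      if (length(ln) == 0L) return(NA_real_)
      as.numeric(sub(paste0("^", key, "\t"), "", ln[1L]))
    }
    n_primers <- sum(grepl("^[ACGTWS]+( \\[degenerate\\])?\t", chunk))
    data.frame(tm = tm, cost = getv("final cost \\(nucleotides\\)"),
               coverage = getv("covered bases"), n_primers = n_primers)
  })
  do.call(rbind, out)
}

#' Reuse totals and percentage reduction from per-level primer counts
#'
#' Given the number of primers at each reuse level (how many distinct
#' primers prime 1x, 2x, ... loci), returns the with-reuse total (the
#' distinct primers actually needed), the equivalent no-reuse total
#' `sum(level * count)` (primers needed for the same coverage if every
#' locus paid for its own primer), and the percentage reduction.
#'
#' @param level_counts Named numeric vector; names are reuse levels.
#' @return List with `with_reuse`, `no_reuse` and `reduction_pct`.
#' @examples
#' reuse_totals(c(`5` = 0.01, `4` = 1.28, `3` = 4.39, `2` = 99.54,
#'                `1` = 437.41))
#' @export
reuse_totals <- function(level_counts) {
  lv <- as.numeric(names(level_counts))
  if (any(is.na(lv))) stop("reuse_totals: names must be reuse levels")
  with_reuse <- sum(level_counts)
  no_reuse <- sum(lv * level_counts)
  list(with_reuse = with_reuse, no_reuse = no_reuse,
       reduction_pct = 100 * (no_reuse - with_reuse) / no_reuse)
}

#' Summarize repeated optimization runs
#'
#' Across-run mean and standard error of cost per covered base, per-reuse-
#' level mean primer counts with standard errors, the equivalent no-reuse
#' totals and the percentage reduction from reuse. Standard error is the
#' sample standard deviation divided by `sqrt(n)`.
#'
#' @param runs List of runs; each a list with `cost`, `coverage`, and
#'   `histogram` (named counts per reuse level, as from
#'   [redundancy_histogram()]).
#' @return List with `n_runs`, `cpb_mean`, `cpb_se`, `levels` (data frame:
#'   `level`, `mean_count`, `se`), `with_reuse_total`, `no_reuse_total`,
#'   `reduction_pct`.
#' @export
summarize_runs <- function(runs) {
  stopifnot(length(runs) >= 2L)
  cpb <- vapply(runs, function(r) r$cost / r$coverage, numeric(1L))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  all_levels <- sort(unique(unlist(lapply(runs, function(r)
    as.integer(names(r$histogram))))))
  counts <- vapply(runs, function(r) {
    out <- stats::setNames(numeric(length(all_levels)), all_levels)
    h <- r$histogram
    out[names(h)] <- as.numeric(h)
    out
  }, numeric(length(all_levels)))
  counts <- matrix(counts, nrow = length(all_levels))
  mean_count <- rowMeans(counts)
  lvl <- data.frame(level = all_levels, mean_count = mean_count,
                    se = apply(counts, 1L, se))
  tot <- reuse_totals(stats::setNames(mean_count, all_levels))
  list(n_runs = length(runs), cpb_mean = mean(cpb), cpb_se = se(cpb),
       levels = lvl, with_reuse_total = tot$with_reuse,
       no_reuse_total = tot$no_reuse, reduction_pct = tot$reduction_pct)
}
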