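#' primertile: minimal-cost reusable degenerate primer sets by MCMC
#'
#' Designs minimal-cost sets of reusable, optionally degenerate (W/S) PCR
#' primers that tile target gene sequences with amplicons. Candidates are
#' enumerated exhaustively per integer melting temperature, screened for
#' hairpins, self-dimers and background redundancy, generalized into
#' W/S-degenerate primers around collated SNPs, and the per-gene amplicon
#' tiling is optimized by Metropolis-Hastings sampling of the design-cost
#' landscape with three greedy proposal generators. The objective is the
#' nucleotide count over the distinct primers of the design, so a primer
#' reused at several loci is paid for once.
#'
#' @keywords internal
"_PACKAGE"

#' Fit a primer design over a melting-temperature range
#'
#' The top-level entry point: takes consensus sequences (and optionally
#' exceptions sequences carrying collated SNPs and a background set for
#' redundancy screening), prepares candidate primers at each integer
#' melting temperature in `[tm_min, tm_max]`, and optimizes each
#' temperature's amplicon tiling by Metropolis-Hastings MCMC. Character
#' inputs may be named sequence vectors or FASTA file paths.
#'
#' @param consensus Named character vector of consensus sequences, a FASTA
#'   path, or a [gene_set()] (in which case `exceptions` is ignored).
#' @param exceptions Optional named character vector or FASTA path of
#'   IUPAC exceptions sequences.
#' @param background Optional named character vector or FASTA path of
#'   background sequences for the redundancy bound.
#' @param config A [primer_config()].
#' @param seed Convenience override of `config$rng_seed`.
#' @return An object of class `primertile` with components `sweep` (a
#'   `tm_sweep`), `summary` (per-temperature metrics), `config`, `genes`.
#' @examples
#' \donttest{
#' fx <- generate_gene_set(n_genes = 4, length = 400, seed = 1)
#' cfg <- primer_config(tm_min = 60, tm_max = 60, n_iterations = 200,
#'                      rng_seed = 1)
#' fit <- primertile(fx$genes, background = fx$background, config = cfg)
#' fit
#' }
#' @export
primertile <- function(consensus, exceptions = NULL, background = NULL,
                       config = primer_config(), seed = NULL) {
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  validate_config(config)
  genes <- if (inherits(consensus, "gene_set")) consensus else {
    cons <- if (is.character(consensus) && length(consensus) == 1L &&
                  file.exists(consensus)) read_fasta(consensus) else consensus
    exc <- if (is.character(exceptions) && length(exceptions) == 1L &&
                 file.exists(exceptions)) read_fasta(exceptions) else exceptions
    gene_set(cons, exc)
  }
  if (is.character(background) && length(background) == 1L &&
        file.exists(background))
    background <- read_fasta(background)
  sweep <- run_tm_sweep(genes, config, background)
  structure(list(sweep = sweep, summary = sweep$summary, config = config,
                 genes = genes), class = "primertile")
}

#' @export
print.primertile <- function(x, ...) {
  cat("primertile design fit\n")
  cat("  genes:", length(x$genes$id), "(", sum(x$genes$length), "bp )\n")
  cat("  Tm range:", x$config$tm_min, "-", x$config$tm_max, "C;",
      x$config$n_iterations, "MCMC iterations per Tm\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
summary.primertile <- function(object, ...) {
  s <- object$summary
  best <- which.min(s$cost_per_base)
  out <- list(summary = s,
              best_tm = if (length(best)) s$tm[best] else NA_integer_,
              histograms = object$sweep$histograms)
  class(out) <- "summary.primertile"
  out
}

#' @export
print.summary.primertile <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat("\nmost economical Tm:", x$best_tm, "C\n")
  for (i in seq_len(nrow(x$summary))) {
    h <- x$histograms[[i]]
    if (h$n_distinct == 0L) next
    cat("  Tm ", x$summary$tm[i], ": reuse histogram [",
        paste(sprintf("%sx:%d", names(h$histogram), h$histogram),
              collapse = " "), "], no-reuse equivalent ", h$no_reuse_total,
        " primers, reduction ", h$reduction_pct, "%\n", sep = "")
  }
  invisible(x)
}

#' Plot a primer design fit
#'
#' With more than one melting temperature: cost and percentage coverage
#' against Tm (the trade-off the sweep exposes). With a single
#' temperature: the best-so-far cost trace of the MCMC run when a trace
#' was kept, otherwise the per-gene amplicon tiling.
#'
#' @param x A `primertile` fit.
#' @param ... Passed to the underlying plot call.
#' @export
plot.primertile <- function(x, ...) {
  s <- x$summary
  if (nrow(s) > 1L) {
    op <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(s$tm, s$cost, type = "b", xlab = "Tm (C)",
                   ylab = "cost (nt)", ...)
    graphics::plot(s$tm, s$pct_coverage, type = "b", xlab = "Tm (C)",
                   ylab = "coverage (%)", ...)
  } else {
    d <- x$sweep$designs[[1L]]
    if (is.null(d)) { graphics::plot.new(); return(invisible(x)) }
    n <- length(d$amps)
    graphics::plot(NULL, xlim = c(0, max(x$genes$length)),
                   ylim = c(0.5, n + 0.5), xlab = "position (bp)",
                   ylab = "gene", yaxt = "n", ...)
    graphics::axis(2, at = seq_len(n), labels = x$genes$id, las = 2,
                   cex.axis = 0.6)
    for (gi in seq_len(n)) {
      graphics::segments(0, gi, x$genes$length[gi], gi, col = "grey70")
      m <- d$amps[[gi]]
      if (nrow(m)) graphics::segments(m[, 1L], gi, m[, 2L], gi, lwd = 4,
                                      col = "steelblue")
    }
  }
  invisible(x)
}

#' Primer table of a fitted design
#'
#' @param x A `primertile` fit.
#' @param tm Melting temperature to extract (default: the most economical).
#' @return Data frame of the distinct primers used at that temperature:
#'   `seq`, `length`, `degeneracy`, `reuse`, `tm`.
#' @export
primers <- function(x, tm = NULL) {
  stopifnot(inherits(x, "primertile"))
  s <- x$summary
  if (is.null(tm)) tm <- s$tm[which.min(s$cost_per_base)]
  i <- match(tm, s$tm)
  if (is.na(i)) stop("no design at Tm ", tm)
  d <- x$sweep$designs[[i]]
  if (is.null(d)) return(data.frame())
  ids <- .design_ids(d$amps)
  uses <- table(ids)
  uid <- as.integer(names(uses))
  ord <- order(d$catalog$rank[uid])
  data.frame(seq = d$catalog$seq[uid][ord],
             length = d$catalog$length[uid][ord],
             degeneracy = d$catalog$n_degenerate[uid][ord],
             reuse = as.integer(uses)[ord],
             tm = d$catalog$tm[uid][ord],
             stringsAsFactors = FALSE)
}
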