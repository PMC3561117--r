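# Design state (per-gene amplicon tilings) and its evaluation metrics:
# cost over distinct primers, coverage, cost per covered base, reuse
# histogram, and validity checking.

# amps: list (one element per gene, in gene_set order) of integer matrices
# with columns start, end (0-based half-open, primer footprints included),
# fwd, rev (candidate indices into the catalogue)
new_design <- function(amps, catalog, genes, cfg, lookup = NULL) {
  structure(list(amps = amps, catalog = catalog, genes = genes, cfg = cfg,
                 lookup = lookup),
            class = "primer_design")
}

.design_ids <- function(amps) {
  ids <- unlist(lapply(amps, function(m) if (nrow(m)) m[, 3:4] else integer(0)),
                use.names = FALSE)
  as.integer(ids)
}

# optimization objective: nucleotides over distinct primers (reuse paid
# once), or over every primer use when reuse costing is disabled
.objective <- function(amps, catalog, reuse_costing = TRUE) {
  ids <- .design_ids(amps)
  if (length(ids) == 0L) return(0L)
  if (reuse_costing) ids <- unique(ids)
  sum(catalog$length[ids])
}

.coverage_one <- function(m) {
  if (nrow(m) == 0L) return(0L)
  o <- order(m[, 1L])
  s <- m[o, 1L]; e <- m[o, 2L]
  tot <- 0L; cs <- s[1L]; ce <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= ce) ce <- max(ce, e[i])
    else { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
  }
  tot + (ce - cs)
}

#' Design cost in nucleotides
#'
#' The optimization objective: the summed length of the *distinct* primer
#' sequences used by the design. A primer reused at several loci is paid
#' for once.
#'
#' @param d A `primer_design`.
#' @return Integer nucleotide count.
#' @export
design_cost <- function(d) {
  stopifnot(inherits(d, "primer_design"))
  .objective(d$amps, d$catalog, reuse_costing = TRUE)
}

#' Design coverage in base pairs
#'
#' Size of the union of amplicon intervals (primer footprints included),
#' summed over genes.
#'
#' @param d A `primer_design`.
#' @return Integer base-pair count.
#' @export
design_coverage <- function(d) {
  stopifnot(inherits(d, "primer_design"))
  sum(vapply(d$amps, .coverage_one, integer(1L)))
}

#' Cost per covered base
#'
#' `cost / coverage`, reported rounded to 2 decimals (the scale on which
#' primer designs are compared).
#'
#' @param cost Nucleotide cost.
#' @param coverage Covered base pairs; must be positive.
#' @return Numeric ratio rounded to 2 decimals.
#' @examples
#' cost_per_covered_base(197, 958)   # 0.21
#' @export
cost_per_covered_base <- function(cost, coverage) {
  if (any(coverage == 0))
    stop("cost_per_covered_base: undefined at zero coverage")
  round(cost / coverage, 2L)
}

#' Primer reuse histogram of a design
#'
#' The reuse level of a primer is the number of amplicons in the design
#' using it (as forward or reverse). Returns the histogram over distinct
#' primers together with the equivalent no-reuse primer count
#' (`sum(level * count)`) and the percentage reduction
#' `100 * (no_reuse - distinct) / no_reuse`.
#'
#' @param d A `primer_design`.
#' @return List with `histogram` (named integer vector, names = reuse
#'   level), `n_distinct`, `no_reuse_total` and `reduction_pct`.
#' @export
redundancy_histogram <- function(d) {
  stopifnot(inherits(d, "primer_design"))
  ids <- .design_ids(d$amps)
  if (length(ids) == 0L)
    return(list(histogram = integer(0), n_distinct = 0L,
                no_reuse_total = 0L, reduction_pct = 0))
  uses <- table(ids)
  hist <- table(as.integer(uses))
  hist <- stats::setNames(as.integer(hist), names(hist))
  n_distinct <- length(uses)
  no_reuse <- sum(as.integer(names(hist)) * hist)
  list(histogram = hist, n_distinct = n_distinct,
       no_reuse_total = no_reuse,
       reduction_pct = round(100 * (no_reuse - n_distinct) / no_reuse, 2L))
}

#' Validate a design against its constraints
#'
#' Checks every amplicon and design invariant: amplicon length within
#' `[amplicon_min, amplicon_max]` and inside its gene; the forward primer
#' has a plus-strand binding site at the amplicon start and the reverse
#' primer a minus-strand site ending at the amplicon end; forward and
#' reverse differ as sequences and do not form a primer-dimer pair; every
#' (forward, reverse) pair is unique across the design. Uncovered gaps
#' between adjacent amplicons larger than `max_gap`, and amplicons nested
#' inside a neighbour whose primers are all single-use, are reported as
#' warnings, not violations.
#'
#' @param d A `primer_design`.
#' @return List with `ok` (flag), `violations` and `warnings` (data frames
#'   with columns `gene`, `amplicon`, `type`, `detail`). Never throws.
#' @export
validate_design <- function(d) {
  stopifnot(inherits(d, "primer_design"))
  cat <- d$catalog; cfg <- d$cfg; genes <- d$genes
  viol <- warn <- list()
  add <- function(lst, gene, amp, type, detail)
    c(lst, list(data.frame(gene = gene, amplicon = amp, type = type,
                           detail = detail, stringsAsFactors = FALSE)))
  uses <- table(.design_ids(d$amps))
  pair_keys <- character(0)
  for (gi in seq_along(d$amps)) {
    m <- d$amps[[gi]]
    if (nrow(m) == 0L) next
    gid <- genes$id[gi]; glen <- genes$length[gi]
    for (k in seq_len(nrow(m))) {
      s <- m[k, 1L]; e <- m[k, 2L]; f <- m[k, 3L]; r <- m[k, 4L]
      len <- e - s
      if (len < cfg$amplicon_min || len > cfg$amplicon_max)
        viol <- add(viol, gid, k, "amplicon_length",
                    sprintf("length %d outside [%d,%d]", len,
                            cfg$amplicon_min, cfg$amplicon_max))
      if (s < 0L || e > glen)
        viol <- add(viol, gid, k, "out_of_gene",
                    sprintf("[%d,%d) outside [0,%d)", s, e, glen))
      fs <- cat$sites
      if (!any(fs$cand == f & fs$gene == gi & fs$start == s & fs$strand == "+"))
        viol <- add(viol, gid, k, "fwd_site",
                    "forward primer has no + site at amplicon start")
      if (!any(fs$cand == r & fs$gene == gi & fs$strand == "-" &
                 fs$start + cat$length[r] == e))
        viol <- add(viol, gid, k, "rev_site",
                    "reverse primer has no - site ending at amplicon end")
      if (cat$seq[f] == cat$seq[r])
        viol <- add(viol, gid, k, "fwd_eq_rev",
                    "forward and reverse are the same sequence")
      else if (check_dimer(cat$seq[f], cat$seq[r]))
        viol <- add(viol, gid, k, "pair_dimer",
                    "forward/reverse pair forms a primer-dimer")
      pair_keys <- c(pair_keys, paste0(f, ".", r))
    }
    # warnings: gaps and nested amplicons
    o <- order(m[, 1L])
    s <- m[o, 1L]; e <- m[o, 2L]
    if (nrow(m) >= 2L) {
      gaps <- s[-1L] - cummax(e)[-nrow(m)]
      big <- which(gaps > cfg$max_gap)
      for (k in big)
        warn <- add(warn, gid, o[k + 1L], "gap",
                    sprintf("uncovered gap of %d bp > max_gap %d",
                            gaps[k], cfg$max_gap))
      for (k in seq_len(nrow(m))) {
        nested_in <- which(m[, 1L] <= m[k, 1L] & m[k, 2L] <= m[, 2L] &
                             seq_len(nrow(m)) != k)
        if (length(nested_in) &&
            uses[as.character(m[k, 3L])] == 1L &&
            uses[as.character(m[k, 4L])] == 1L)
          warn <- add(warn, gid, k, "nested_single_use",
                      "amplicon nested in a neighbour with single-use primers")
      }
    }
  }
  dup <- duplicated(pair_keys)
  if (any(dup))
    viol <- add(viol, NA_character_, NA_integer_, "pair_duplicate",
                paste("duplicated primer pair(s):",
                      paste(unique(pair_keys[dup]), collapse = ", ")))
  empty <- data.frame(gene = character(0), amplicon = integer(0),
                      type = character(0), detail = character(0),
                      stringsAsFactors = FALSE)
  viol <- if (length(viol)) do.call(rbind, viol) else empty
  warn <- if (length(warn)) do.call(rbind, warn) else empty
  list(ok = nrow(viol) == 0L, violations = viol, warnings = warn)
}

#' @export
print.primer_design <- function(x, ...) {
  n_amp <- sum(vapply(x$amps, nrow, integer(1L)))
  cov <- design_coverage(x)
  cost <- design_cost(x)
  cat("primer_design: ", n_amp, " amplicon(s) over ",
      sum(vapply(x$amps, nrow, integer(1L)) > 0L), "/",
      length(x$amps), " gene(s)\n",
      "  cost ", cost, " nt over ",
      length(unique(.design_ids(x$amps))), " distinct primer(s), coverage ",
      cov, " bp", sep = "")
  if (cov > 0L) cat(", cost/base ", cost_per_covered_base(cost, cov), sep = "")
  cat("\n")
  invisible(x)
}
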