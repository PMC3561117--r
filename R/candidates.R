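# Candidate primer preparation: exhaustive enumeration per target melting
# temperature, SNP-aware W/S forcing, self-dimer/hairpin screening,
# background redundancy bounds, degenerate generalization, and weighting.

#' Enumerate candidate primers at one target melting temperature
#'
#' Scans every substring of every consensus sequence, on both strands, with
#' length in `[primer_len_min, primer_len_max]`, keeping those whose rounded
#' melting temperature equals `tm_target`, whose footprint contains no `N`,
#' and which satisfy the SNP constraints of the gene's exceptions sequence
#' (SNP columns with base set `{A,T}` force a W, `{C,G}` force an S, any
#' other set invalidates the footprint; forced positions count toward
#' `max_degeneracy`). Candidates are de-duplicated by sequence with merged
#' binding-site lists; a candidate's redundancy is its number of distinct
#' binding sites over the target set.
#'
#' Minus-strand sites are stored by the plus-strand start of the reverse-
#' complement match; all coordinates are 0-based, half-open.
#'
#' @param genes A [gene_set()].
#' @param tm_target Integer target melting temperature (degrees centigrade).
#' @param cfg A [primer_config()].
#' @return A `primer_catalog`: list with per-candidate `seq`, `length`,
#'   `tm`, `n_degenerate`, `redundancy`, `rank` (weight order, 1 = best) and
#'   a `sites` data frame (`cand`, `gene`, `start`, `strand`).
#' @seealso [prepare_candidates()] for the full screening pipeline.
#' @export
enumerate_candidates <- function(genes, tm_target, cfg) {
  stopifnot(inherits(genes, "gene_set"))
  seqs <- character(0); lens <- integer(0); ndegs <- integer(0)
  site_gene <- integer(0); site_start <- integer(0); site_strand <- character(0)
  for (gi in seq_along(genes$id)) {
    pre <- .gene_precompute(genes, gi)
    n <- genes$length[gi]
    for (L in cfg$primer_len_min:cfg$primer_len_max) {
      if (L > n) next
      i <- seq_len(n - L + 1L)                       # 1-based window starts
      ngc <- pre$cg[i + L] - pre$cg[i]
      nf  <- pre$cf[i + L] - pre$cf[i]
      ninv <- pre$ci[i + L] - pre$ci[i]
      ok <- ninv == 0L & nf <= cfg$max_degeneracy &
        round(.tm_from_counts(ngc, L)) == tm_target
      if (!any(ok)) next
      i <- i[ok]
      w <- substring(pre$s_mod, i, i + L - 1L)
      wrc <- revcomp(w)
      k <- length(i)
      seqs <- c(seqs, w, wrc)
      lens <- c(lens, rep.int(L, 2L * k))
      ndegs <- c(ndegs, rep.int(nf[ok], 2L))
      site_gene <- c(site_gene, rep.int(gi, 2L * k))
      site_start <- c(site_start, i - 1L, i - 1L)
      site_strand <- c(site_strand, rep("+", k), rep("-", k))
    }
  }
  .build_catalog(seqs, lens, ndegs, site_gene, site_start, site_strand,
                 tm_target, genes)
}

# per-gene position annotations: GC indicator, forced-degeneracy indicator,
# invalid indicator, and the consensus with SNP columns replaced by W/S
.gene_precompute <- function(genes, gi) {
  s <- strsplit(genes$consensus[gi], "", fixed = TRUE)[[1L]]
  gc <- as.integer(s %in% c("G", "C"))
  inv <- as.integer(s == "N")
  forced <- integer(length(s))
  s_mod <- s
  e <- genes$exceptions[gi]
  if (!is.na(e)) {
    ec <- strsplit(e, "", fixed = TRUE)[[1L]]
    diff <- which(ec != s & s != "N")
    for (j in diff) {
      set <- sort(.iupac_bases(ec[j]))
      if (identical(set, c("A", "T"))) { s_mod[j] <- "W"; forced[j] <- 1L }
      else if (identical(set, c("C", "G"))) { s_mod[j] <- "S"; forced[j] <- 1L }
      else inv[j] <- 1L                   # not Tm-neutral: footprint invalid
    }
  }
  list(s_mod = paste(s_mod, collapse = ""),
       cg = c(0L, cumsum(gc)),
       cf = c(0L, cumsum(forced)),
       ci = c(0L, cumsum(inv)))
}

.build_catalog <- function(seqs, lens, ndegs, site_gene, site_start,
                           site_strand, tm_target, genes) {
  if (length(seqs) == 0L) {
    return(structure(list(seq = character(0), length = integer(0),
                          tm = numeric(0), n_degenerate = integer(0),
                          redundancy = integer(0), rank = integer(0),
                          sites = data.frame(cand = integer(0),
                                             gene = integer(0),
                                             start = integer(0),
                                             strand = character(0)),
                          tm_target = tm_target, gene_ids = genes$id),
                     class = "primer_catalog"))
  }
  useq <- unique(seqs)
  uid <- match(seqs, useq)
  first <- match(seq_along(useq), uid)
  cat <- structure(list(
    seq = useq,
    length = lens[first],
    tm = melting_temperature(useq),
    n_degenerate = ndegs[first],
    redundancy = tabulate(uid, nbins = length(useq)),
    rank = integer(length(useq)),
    sites = data.frame(cand = uid, gene = site_gene, start = site_start,
                       strand = site_strand, stringsAsFactors = FALSE),
    tm_target = tm_target,
    gene_ids = genes$id), class = "primer_catalog")
  .rank_catalog(cat)
}

# weight order: higher redundancy, then lower degeneracy, then shorter
# (cheaper), then lexicographic for determinism
.rank_catalog <- function(cat) {
  o <- order(-cat$redundancy, cat$n_degenerate, cat$length, cat$seq)
  cat$rank <- integer(length(o)); cat$rank[o] <- seq_along(o)
  cat
}

.cat_subset <- function(cat, keep) {
  keep <- which(keep)
  remap <- integer(length(cat$seq)); remap[keep] <- seq_along(keep)
  s <- cat$sites[cat$sites$cand %in% keep, , drop = FALSE]
  s$cand <- remap[s$cand]
  cat$seq <- cat$seq[keep]; cat$length <- cat$length[keep]
  cat$tm <- cat$tm[keep]; cat$n_degenerate <- cat$n_degenerate[keep]
  cat$redundancy <- cat$redundancy[keep]
  cat$sites <- s[order(s$cand, s$gene, s$start), , drop = FALSE]
  rownames(cat$sites) <- NULL
  .rank_catalog(cat)
}

#' @export
print.primer_catalog <- function(x, ...) {
  cat("primer_catalog: ", length(x$seq), " candidate primer(s) at Tm ",
      x$tm_target, " C; ", sum(x$redundancy >= 2L),
      " reusable (redundancy >= 2), ", sum(x$n_degenerate > 0L),
      " degenerate\n", sep = "")
  invisible(x)
}

#' Primer weighting order
#'
#' Total preference order over candidates: higher redundancy (reuse
#' potential) first, ties by lower degeneracy, then by shorter length
#' (cheaper under the nucleotide-count cost), then lexicographically for
#' determinism. Returns the rank of each candidate (1 = most preferred).
#'
#' @param catalog A `primer_catalog`.
#' @return Integer rank vector aligned with `catalog$seq`.
#' @export
primer_weight <- function(catalog) {
  stopifnot(inherits(catalog, "primer_catalog"))
  .rank_catalog(catalog)$rank
}

#' Apply SNP constraints to one primer footprint
#'
#' For a footprint on a gene with an exceptions sequence: every column whose
#' ambiguity code differs from the consensus base becomes W (base set
#' `{A,T}`) or S (`{C,G}`); any other base set (not melting-temperature
#' neutral) invalidates the candidate at that site. Forced positions count
#' toward the degeneracy budget.
#'
#' @param genes A [gene_set()].
#' @param gene_id Gene identifier.
#' @param start 0-based footprint start on the plus strand.
#' @param length Footprint length.
#' @param strand `"+"` or `"-"` (the returned primer sequence is the
#'   reverse complement of the footprint for `"-"`).
#' @return List with `valid` (flag), `seq` (adjusted primer or `NA`), and
#'   `n_forced` (count of forced W/S positions).
#' @export
apply_snp_constraints <- function(genes, gene_id, start, length,
                                  strand = "+") {
  stopifnot(inherits(genes, "gene_set"), strand %in% c("+", "-"))
  gi <- match(gene_id, genes$id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  if (start < 0L || start + length > genes$length[gi])
    stop("footprint outside gene ", gene_id)
  pre <- .gene_precompute(genes, gi)
  i <- start + 1L
  if (pre$ci[i + length] - pre$ci[i] > 0L)
    return(list(valid = FALSE, seq = NA_character_, n_forced = NA_integer_))
  w <- substr(pre$s_mod, i, i + length - 1L)
  if (strand == "-") w <- revcomp(w)
  list(valid = TRUE, seq = w,
       n_forced = pre$cf[i + length] - pre$cf[i])
}

#' Count exact occurrences of candidate primers in a background set
#'
#' Number of exact matches of any concrete expansion of each candidate on
#' either strand of the background sequences (an internal exact-match
#' substring search; the search is isolated here so an external aligner
#' could be substituted). Candidates matching the background more than
#' `cfg$max_redundancy` times are to be discarded as low-complexity or
#' repeat-borne.
#'
#' @param catalog A `primer_catalog`.
#' @param background Named character vector of background sequences.
#' @return Integer vector of occurrence counts aligned with `catalog$seq`.
#' @export
count_background_occurrences <- function(catalog, background) {
  stopifnot(inherits(catalog, "primer_catalog"), is.character(background))
  nq <- length(catalog$seq)
  counts <- integer(nq)
  if (nq == 0L || length(background) == 0L) return(counts)
  background <- toupper(background)
  texts <- c(background, revcomp(background))
  # expansion table: query string -> parent candidate
  is_deg <- grepl("[WS]", catalog$seq)
  qseq <- as.list(catalog$seq)
  qseq[is_deg] <- lapply(catalog$seq[is_deg], expand_degenerate)
  parent <- rep.int(seq_len(nq), lengths(qseq))
  qseq <- unlist(qseq, use.names = FALSE)
  qlen <- nchar(qseq)
  for (L in unique(qlen)) {
    sel <- qlen == L
    qs <- qseq[sel]; qp <- parent[sel]
    hit <- integer(length(qs))
    for (txt in texts) {
      n <- nchar(txt)
      if (n < L) next
      km <- substring(txt, 1:(n - L + 1L), L:n)
      m <- match(km, qs)
      m <- m[!is.na(m)]
      if (length(m)) hit <- hit + tabulate(m, nbins = length(qs))
    }
    counts[qp] <- counts[qp] + hit  # expansions are distinct strings, so
  }                                 # summing counts distinct loci once
  counts
}

#' Generalize candidates into W/S-degenerate primers
#'
#' For groups of candidates that become identical when every A/T position is
#' collapsed to W and every G/C position to S, enumerates the degenerate
#' primers (up to `cfg$max_degeneracy` W/S positions) that subsume at least
#' two distinct catalogue members; each retained degenerate primer carries
#' the union of its members' binding sites, so its redundancy is reassessed
#' over the whole target set. The output is the input catalogue merged with
#' the retained degenerates, de-duplicated and re-ranked. Newly created
#' degenerates are screened (hairpins/self-dimers through their expansions,
#' and background redundancy when `background` is given).
#'
#' @param catalog A `primer_catalog` (already screened).
#' @param cfg A [primer_config()].
#' @param background Optional named character vector for redundancy bounds.
#' @return The augmented `primer_catalog`.
#' @export
generate_degenerates <- function(catalog, cfg, background = NULL) {
  stopifnot(inherits(catalog, "primer_catalog"))
  n <- length(catalog$seq)
  if (n == 0L || cfg$max_degeneracy == 0L) return(catalog)
  key <- paste0(nchar(catalog$seq), ":",
                chartr("ATGC", "WWSS", catalog$seq))
  grp <- split(seq_len(n), key)
  grp <- grp[lengths(grp) >= 2L]
  new_seq <- character(0); new_members <- list()
  for (g in grp) {
    res <- .degenerates_for_group(catalog$seq[g], cfg$max_degeneracy)
    for (r in res) {
      new_seq <- c(new_seq, r$seq)
      new_members <- c(new_members, list(g[r$members]))
    }
  }
  if (length(new_seq) == 0L) return(catalog)
  dup <- duplicated(new_seq) | new_seq %in% catalog$seq
  new_seq <- new_seq[!dup]; new_members <- new_members[!dup]
  if (length(new_seq) == 0L) return(catalog)
  # screen the new degenerates
  ok <- !vapply(new_seq, function(s) {
    check_hairpin(s) || check_dimer(s, s)
  }, logical(1L))
  new_seq <- new_seq[ok]; new_members <- new_members[ok]
  if (length(new_seq) && !is.null(background)) {
    tmp <- .build_catalog(new_seq, nchar(new_seq), .n_degenerate(new_seq),
                          rep.int(1L, length(new_seq)),
                          rep.int(0L, length(new_seq)),
                          rep("+", length(new_seq)),
                          catalog$tm_target,
                          structure(list(id = catalog$gene_ids),
                                    class = "gene_set"))
    # .build_catalog sorts by seq dedup order == input order here
    bg <- count_background_occurrences(tmp, background)
    keep <- bg[match(new_seq, tmp$seq)] <= cfg$max_redundancy
    new_seq <- new_seq[keep]; new_members <- new_members[keep]
  }
  if (length(new_seq) == 0L) return(catalog)
  add_sites <- do.call(rbind, lapply(seq_along(new_seq), function(k) {
    s <- catalog$sites[catalog$sites$cand %in% new_members[[k]], , drop = FALSE]
    s <- unique(s[c("gene", "start", "strand")])
    cbind(cand = length(catalog$seq) + k, s)
  }))
  red <- as.integer(table(factor(add_sites$cand,
                                 levels = length(catalog$seq) + seq_along(new_seq))))
  keep_red <- red <= cfg$max_redundancy
  catalog$seq <- c(catalog$seq, new_seq)
  catalog$length <- c(catalog$length, nchar(new_seq))
  catalog$tm <- c(catalog$tm, melting_temperature(new_seq))
  catalog$n_degenerate <- c(catalog$n_degenerate, .n_degenerate(new_seq))
  catalog$redundancy <- c(catalog$redundancy, red)
  catalog$sites <- rbind(catalog$sites, add_sites)
  catalog <- .cat_subset(catalog, c(rep(TRUE, n), keep_red))
  catalog
}

# All W/S generalizations within one collapse class that subsume >= 2
# members; returns list of list(seq, members (indices into `seqs`)).
.degenerates_for_group <- function(seqs, max_deg) {
  g <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  subsets <- if (g <= 10L) {
    unlist(lapply(2:g, function(k) combn(g, k, simplify = FALSE)),
           recursive = FALSE)
  } else {
    combn(g, 2L, simplify = FALSE)   # large classes: pairwise only
  }
  out <- list(); seen <- character(0)
  for (ss in subsets) {
    sub <- chars[ss, , drop = FALSE]
    col_mixed <- apply(sub, 2L, function(col) length(unique(col)) > 1L)
    merged <- sub[1L, ]
    ok <- TRUE
    for (j in which(col_mixed)) {
      u <- unique(sub[, j])
      if (all(u %in% c("A", "T", "W"))) merged[j] <- "W"
      else if (all(u %in% c("C", "G", "S"))) merged[j] <- "S"
      else { ok <- FALSE; break }     # cannot happen within a W/S class,
    }                                 # kept as a guard
    if (!ok) next
    dseq <- paste(merged, collapse = "")
    if (.n_degenerate(dseq) > max_deg) next
    if (dseq %in% seen) next
    seen <- c(seen, dseq)
    # all members subsumed by dseq (member char within expansion set)
    mvec <- vapply(seq_len(g), function(i) {
      all(chars[i, ] == merged |
            (merged == "W" & chars[i, ] %in% c("A", "T")) |
            (merged == "S" & chars[i, ] %in% c("C", "G")))
    }, logical(1L))
    if (sum(mvec) >= 2L)
      out[[length(out) + 1L]] <- list(seq = dseq, members = which(mvec))
  }
  out
}

#' Full candidate preparation pipeline
#'
#' The three preparation stages in order: (1) exhaustive enumeration at the
#' target melting temperature (SNP-aware, both strands, de-duplicated);
#' (2) removal of hairpin-forming and self-dimerizing primers, and of
#' primers whose exact-match redundancy over the background (or, absent a
#' background, over the target set) exceeds `cfg$max_redundancy`;
#' (3) recursive W/S-degenerate generalization with redundancy reassessment.
#'
#' @param genes A [gene_set()].
#' @param tm_target Integer target melting temperature.
#' @param cfg A [primer_config()].
#' @param background Optional named character vector of background
#'   sequences used for the redundancy bound.
#' @return A screened, weighted `primer_catalog`.
#' @export
prepare_candidates <- function(genes, tm_target, cfg, background = NULL) {
  cat <- enumerate_candidates(genes, tm_target, cfg)
  if (length(cat$seq) == 0L) return(cat)
  cat <- .cat_subset(cat, !.screen_fail(cat$seq))
  if (length(cat$seq) == 0L) return(cat)
  if (!is.null(background)) {
    bg <- count_background_occurrences(cat, background)
    cat <- .cat_subset(cat, bg <= cfg$max_redundancy)
  }
  cat <- .cat_subset(cat, cat$redundancy <= cfg$max_redundancy)
  if (length(cat$seq) == 0L) return(cat)
  generate_degenerates(cat, cfg, background)
}
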