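# Synthetic fixture generator: consensus/exceptions/background FASTA trios
# with known ground truth (planted reusable priming sites, injected SNPs),
# so every pipeline stage is testable without external data.

#' Generate a synthetic gene set with planted priming sites and SNPs
#'
#' Emulates a transcriptome-scale primer-design input: `n_genes` gene
#' sequences of i.i.d. bases at `gc_target` GC fraction (defaults mimic a
#' temperate-cereal coding-sequence composition); `n_shared_sites` distinct
#' motifs of `motif_len` nt, each planted at `site_multiplicity`
#' non-overlapping loci spread across genes (the reusable priming sites);
#' SNPs injected per column at rate `snp_rate`, 80% of them
#' melting-temperature neutral ({A,T} or {C,G}) and 20% non-neutral so the
#' SNP rejection path is exercised. Planted motifs are built with a GC
#' count such that their rounded melting temperature equals `motif_tm`,
#' and re-rolled until they pass the hairpin/self-dimer screens and occur
#' nowhere else in the gene set, so they are guaranteed to survive
#' enumeration at that temperature with redundancy equal to their
#' multiplicity. SNPs are never injected inside planted footprints. The
#' background is the concatenation of the genes plus a decoy sequence.
#' Fully reproducible from `seed`.
#'
#' @param n_genes Number of genes (default 30).
#' @param length Gene length in bp (default 1000).
#' @param gc_target GC fraction of the generated sequence (default 0.55).
#' @param n_shared_sites Number of distinct planted motifs (default 8).
#' @param site_multiplicity Loci per planted motif (default 3).
#' @param snp_rate Per-column SNP probability (default 0.005).
#' @param seed RNG seed.
#' @param motif_tm Integer target melting temperature(s) of planted motifs
#'   (default 60). May be a vector, paired with `n_shared_sites`, to plant
#'   a ladder of reusable sites across a temperature range (real conserved
#'   repeats are not concentrated at a single temperature).
#' @param motif_len Planted motif length (default 20).
#' @param decoy_length Extra background decoy sequence length (default 2000).
#' @param gc_profile Optional numeric vector of segmental GC fractions.
#'   When given, each gene cycles through these values in blocks of
#'   `segment_len` bp, emulating the local GC heterogeneity of real coding
#'   sequence (GC3 gradients, domain structure) that keeps priming sites
#'   available across a melting-temperature range; `gc_target` is ignored
#'   for the genes (the decoy uses the profile mean).
#' @param segment_len Segment length for `gc_profile` (default 120).
#' @return List with `genes` (a [gene_set()]), `background` (named
#'   character vector), and `truth` (class `synthetic_truth`: `motifs`
#'   data frame with `motif`, `gene`, `pos`, `strand`; `snps` data frame
#'   with `gene`, `pos`, `bases`, `neutral`; `gc_target`; `seed`).
#' @export
generate_gene_set <- function(n_genes = 30L, length = 1000L,
                              gc_target = 0.55, n_shared_sites = 8L,
                              site_multiplicity = 3L, snp_rate = 0.005,
                              seed = 1L, motif_tm = 60L, motif_len = 20L,
                              decoy_length = 2000L, gc_profile = NULL,
                              segment_len = 120L) {
  stopifnot(n_genes >= 1L, length >= 50L, gc_target > 0, gc_target < 1)
  if (length(motif_tm) > 1L || length(n_shared_sites) > 1L) {
    k <- max(length(motif_tm), length(n_shared_sites))
    motif_tm <- rep_len(motif_tm, k)
    n_shared_sites <- rep_len(n_shared_sites, k)
  }
  if (sum(n_shared_sites) * site_multiplicity * motif_len >
        n_genes * length / 2)
    stop("generate_gene_set: planted sites do not fit without overlap")
  set.seed(seed)
  rand_at <- function(n, gc) paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = "")
  rand_seq <- if (is.null(gc_profile)) {
    function(n) rand_at(n, gc_target)
  } else {
    function(n) {
      segs <- character(0); done <- 0L; i <- 0L
      while (done < n) {
        w <- min(segment_len, n - done)
        segs <- c(segs, rand_at(w, gc_profile[i %% length(gc_profile) + 1L]))
        done <- done + w; i <- i + 1L
      }
      paste(segs, collapse = "")
    }
  }
  gene_mat <- lapply(seq_len(n_genes), function(i)
    strsplit(rand_seq(length), "")[[1L]])

  # a motif with rounded Tm exactly `tm`: pick among the (length, GC count)
  # pairs that achieve it (the composition formula cannot reach every
  # integer Tm at a fixed length)
  make_motif <- function(tm) {
    ls <- 18:27                       # primer-length range
    ngc <- round(16.4 + (tm - 64.9) * ls / 41)
    ok <- ngc >= 0L & ngc <= ls & round(.tm_from_counts(ngc, ls)) == tm
    if (!any(ok))
      stop("generate_gene_set: motif_tm ", tm, " unreachable")
    # prefer lengths near motif_len among the achievable pairs
    ok <- ok & abs(ls - motif_len) <= min(abs(ls[ok] - motif_len)) + 2L
    pick <- which(ok)[sample.int(sum(ok), 1L)]
    L <- ls[pick]; k <- ngc[pick]
    pos_gc <- sample.int(L, k)
    ch <- character(L)
    ch[pos_gc] <- sample(c("G", "C"), k, replace = TRUE)
    ch[-pos_gc] <- sample(c("A", "T"), L - k, replace = TRUE)
    paste(ch, collapse = "")
  }
  motifs <- character(0); motif_tms <- integer(0)
  for (k in seq_along(motif_tm)) {
    got <- 0L
    while (got < n_shared_sites[k]) {
      m <- make_motif(motif_tm[k])
      if (m %in% motifs) next
      if (check_hairpin(m) || check_dimer(m, m)) next
      motifs <- c(motifs, m); motif_tms <- c(motif_tms, motif_tm[k])
      got <- got + 1L
    }
  }

  # non-overlapping slots across genes; motif copies spread over distinct
  # genes where possible
  occupied <- lapply(seq_len(n_genes), function(i) integer(0))
  placements <- list()
  for (mi in seq_along(motifs)) {
    gpool <- sample(rep_len(seq_len(n_genes), max(n_genes, site_multiplicity)))
    placed <- 0L; tries <- 0L
    while (placed < site_multiplicity) {
      tries <- tries + 1L
      if (tries > 2000L) stop("generate_gene_set: cannot place motifs")
      gi <- if (placed < length(gpool)) gpool[placed + 1L]
            else sample.int(n_genes, 1L)
      mlen <- nchar(motifs[mi])
      pos <- sample.int(length - mlen + 1L, 1L)        # 1-based
      span <- pos:(pos + mlen - 1L)
      if (any(span %in% occupied[[gi]])) { gpool <- sample(gpool); next }
      occupied[[gi]] <- c(occupied[[gi]], span)
      gene_mat[[gi]][span] <- strsplit(motifs[mi], "")[[1L]]
      placements[[length(placements) + 1L]] <-
        data.frame(motif = motifs[mi], gene = gi, pos = pos - 1L,
                   strand = "+", stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  consensus <- vapply(gene_mat, paste, character(1L), collapse = "")
  names(consensus) <- sprintf("gene%03d", seq_len(n_genes))

  # verify planted motifs occur at exactly their listed loci
  if (length(motifs)) {
    occ <- .count_exact(motifs, consensus)
    if (any(occ != site_multiplicity)) {
      return(generate_gene_set(n_genes, length, gc_target, n_shared_sites,
                               site_multiplicity, snp_rate,
                               seed = seed + 7919L, motif_tm = motif_tm,
                               motif_len = motif_len,
                               decoy_length = decoy_length,
                               gc_profile = gc_profile,
                               segment_len = segment_len))
    }
  }

  # SNP injection (outside planted footprints)
  exc_mat <- gene_mat
  snps <- list()
  for (gi in seq_len(n_genes)) {
    free <- setdiff(seq_len(length), occupied[[gi]])
    hit <- free[stats::runif(base::length(free)) < snp_rate]
    for (pos in hit) {
      b <- gene_mat[[gi]][pos]
      neutral <- stats::runif(1L) < 0.8
      set <- if (neutral) {
        if (b %in% c("A", "T")) c("A", "T") else c("C", "G")
      } else {
        other <- setdiff(c("A", "C", "G", "T"),
                         if (b %in% c("A", "T")) c("A", "T") else c("C", "G"))
        sort(c(b, sample(other, 1L)))
      }
      exc_mat[[gi]][pos] <- .iupac_code_for(set)
      snps[[base::length(snps) + 1L]] <-
        data.frame(gene = gi, pos = pos - 1L,
                   bases = paste(set, collapse = ""),
                   neutral = neutral, stringsAsFactors = FALSE)
    }
  }
  exceptions <- vapply(exc_mat, paste, character(1L), collapse = "")
  names(exceptions) <- names(consensus)

  decoy_gc <- if (is.null(gc_profile)) gc_target else mean(gc_profile)
  decoy <- c(decoy = rand_at(decoy_length, decoy_gc))
  background <- c(consensus, decoy)
  truth <- structure(list(
    motifs = if (base::length(placements)) do.call(rbind, placements)
             else data.frame(motif = character(0), gene = integer(0),
                             pos = integer(0), strand = character(0)),
    snps = if (base::length(snps)) do.call(rbind, snps)
           else data.frame(gene = integer(0), pos = integer(0),
                           bases = character(0), neutral = logical(0)),
    gc_target = gc_target, seed = seed, motif_tm = motif_tms),
    class = "synthetic_truth")
  list(genes = gene_set(consensus, exceptions), background = background,
       truth = truth)
}

# exact occurrence counts of concrete motifs over both strands of texts
.count_exact <- function(motifs, texts) {
  counts <- integer(length(motifs))
  for (txt in c(texts, revcomp(texts))) {
    n <- nchar(txt)
    for (L in unique(nchar(motifs))) {
      if (n < L) next
      km <- substring(txt, 1:(n - L + 1L), L:n)
      sel <- which(nchar(motifs) == L)
      m <- match(km, motifs[sel])
      m <- m[!is.na(m)]
      if (length(m)) counts[sel] <- counts[sel] + tabulate(m, nbins = length(sel))
    }
  }
  counts
}

#' Write a synthetic gene set to FASTA files
#'
#' Emits `<prefix>.consensus.fasta`, `<prefix>.exceptions.fasta`,
#' `<prefix>.background.fasta` and a `<prefix>.truth.tsv` table of planted
#' motif loci.
#'
#' @param x Result of [generate_gene_set()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_gene_set <- function(x, prefix) {
  cons <- stats::setNames(x$genes$consensus, x$genes$id)
  exc <- stats::setNames(x$genes$exceptions, x$genes$id)
  exc <- exc[!is.na(exc)]
  paths <- c(paste0(prefix, ".consensus.fasta"),
             paste0(prefix, ".exceptions.fasta"),
             paste0(prefix, ".background.fasta"),
             paste0(prefix, ".truth.tsv"))
  write_fasta(cons, paths[1L])
  write_fasta(exc, paths[2L])
  write_fasta(x$background, paths[3L])
  utils::write.table(x$truth$motifs, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
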