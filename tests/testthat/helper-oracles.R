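# Independent brute-force oracles and fixture builders. These deliberately
# re-derive every quantity with naive loops, independently of the package's
# vectorized implementations.

BASES <- c("A", "C", "G", "T")

bf_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", W = "W", S = "S", N = "N")
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
}

bf_expand <- function(p) {
  ch <- strsplit(p, "")[[1]]
  out <- ""
  for (c in ch) {
    alt <- switch(c, W = c("A", "T"), S = c("G", "C"), c)
    out <- as.vector(outer(out, alt, paste0))
  }
  sort(unique(out))
}

bf_tm <- function(s) {
  ch <- strsplit(s, "")[[1]]
  64.9 + 41 * (sum(ch %in% c("G", "C", "S")) - 16.4) / length(ch)
}

# sliding-window complementarity oracle for the dimer rule
bf_dimer1 <- function(p, q, end_len = 5, match_len = 8) {
  lp <- nchar(p); lq <- nchar(q)
  p3 <- substr(p, lp - end_len + 1, lp)
  for (i in seq_len(lq - end_len + 1))
    if (substr(q, i, i + end_len - 1) == bf_revcomp(p3)) return(TRUE)
  q3 <- substr(q, lq - end_len + 1, lq)
  for (i in seq_len(lp - end_len + 1))
    if (substr(p, i, i + end_len - 1) == bf_revcomp(q3)) return(TRUE)
  for (i in seq_len(lp - match_len + 1))
    for (j in seq_len(lq - match_len + 1))
      if (substr(p, i, i + match_len - 1) ==
            bf_revcomp(substr(q, j, j + match_len - 1))) return(TRUE)
  FALSE
}

bf_dimer <- function(p, q, end_len = 5, match_len = 8) {
  for (pe in bf_expand(p)) for (qe in bf_expand(q))
    if (bf_dimer1(pe, qe, end_len, match_len)) return(TRUE)
  FALSE
}

# all-segment-pairs oracle for the hairpin rule
bf_hairpin <- function(p, stem = 4, loop = 3) {
  for (pe in bf_expand(p)) {
    n <- nchar(pe)
    for (i in seq_len(n - stem + 1)) {
      for (j in seq_len(n - stem + 1)) {
        if (j < i + stem + loop) next
        if (substr(pe, j, j + stem - 1) ==
              bf_revcomp(substr(pe, i, i + stem - 1))) return(TRUE)
      }
    }
  }
  FALSE
}

# naive both-strand substring enumeration (SNP-unaware; use on genes
# without exceptions)
bf_enumerate <- function(consensus, tm_target, len_min, len_max) {
  hits <- list()
  for (gi in seq_along(consensus)) {
    s <- consensus[[gi]]
    n <- nchar(s)
    for (L in len_min:len_max) {
      if (L > n) next
      for (i in seq_len(n - L + 1)) {
        w <- substr(s, i, i + L - 1)
        if (grepl("N", w)) next
        if (round(bf_tm(w)) != tm_target) next
        hits[[length(hits) + 1]] <- data.frame(
          seq = w, gene = gi, start = i - 1, strand = "+")
        hits[[length(hits) + 1]] <- data.frame(
          seq = bf_revcomp(w), gene = gi, start = i - 1, strand = "-")
      }
    }
  }
  if (!length(hits)) return(data.frame(seq = character(0)))
  do.call(rbind, hits)
}

# exact-match count of expansions of p over both strands of texts
bf_count <- function(p, texts) {
  tot <- 0L
  for (pe in bf_expand(p)) {
    L <- nchar(pe)
    for (txt in c(texts, bf_revcomp(texts))) {
      n <- nchar(txt)
      if (n < L) next
      for (i in seq_len(n - L + 1))
        if (substr(txt, i, i + L - 1) == pe) tot <- tot + 1L
    }
  }
  tot
}

rand_oligo <- function(len, gc = 0.5) {
  paste(sample(BASES, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a minimal hand-made catalogue for direct metric tests
fake_catalog <- function(seqs, sites, tm_target = 60, gene_ids = "g1") {
  cat <- structure(list(
    seq = seqs, length = nchar(seqs),
    tm = vapply(seqs, bf_tm, numeric(1)),
    n_degenerate = nchar(seqs) - nchar(gsub("[WS]", "", seqs)),
    redundancy = as.integer(table(factor(sites$cand,
                                         levels = seq_along(seqs)))),
    rank = seq_along(seqs), sites = sites,
    tm_target = tm_target, gene_ids = gene_ids),
    class = "primer_catalog")
  cat
}

# small-instance builder for the exhaustive-optimum comparison: one short
# gene, fixed primer length 20, a melting temperature chosen so that the
# screened catalogue is small and a spanning amplicon is admissible
make_oracle_instance <- function(seed) {
  cfg0 <- primer_config(primer_len_min = 20, primer_len_max = 20,
                        amplicon_min = 50, n_iterations = 5000,
                        tm_min = 50, tm_max = 70)
  for (off in 0:30) {
    fx <- generate_gene_set(n_genes = 1, length = 130, gc_target = 0.5,
                            n_shared_sites = 0, snp_rate = 0,
                            seed = seed + 1000L * off)
    for (t in 50:70) {
      ct <- prepare_candidates(fx$genes, t, cfg0)
      if (length(ct$seq) < 2 || length(ct$seq) > 12) next
      orc <- tryCatch(oracle_optimal_cost(fx$genes, ct, cfg0),
                      error = function(e) NULL)
      if (is.null(orc) || orc$n_feasible < 2) next
      # the spanning pair must itself be an admissible amplicon, so the
      # maximal coverage is reachable with a single pair
      st <- ct$sites
      fmin <- min(st$start[st$strand == "+"])
      emax <- max(st$start[st$strand == "-"] +
                    ct$length[st$cand[st$strand == "-"]])
      if (emax - fmin < cfg0$amplicon_min) next
      if (orc$coverage != emax - fmin) next
      if (orc$cost != 40L) next   # spanning pair admissible: one amplicon,
                                  # two fixed-length primers
      cfg <- cfg0; cfg$tm_min <- cfg$tm_max <- as.integer(t)
      return(list(genes = fx$genes, catalog = ct, cfg = cfg, oracle = orc))
    }
  }
  stop("no oracle instance found")
}
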