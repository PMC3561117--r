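# Primer-dimer and hairpin screening.
#
# Thresholds (3'-terminal 5-mer complementarity or a contiguous reverse-
# complement duplex of >= 8 bp between two oligos; hairpin stem >= 4 nt with
# loop >= 3 nt) are conventional screening defaults, exposed as arguments.

#' Cross-dimer check between two primers
#'
#' Two oligos are flagged as a dimer pair when the 3'-terminal `end_len`-mer
#' of either is the reverse complement of any window of the other (a primed
#' extensible 3' duplex), or when the two share a contiguous reverse-
#' complement match of at least `match_len` bp. Degenerate (W/S) oligos are
#' checked through all concrete expansions: any dimerizing expansion pair
#' flags the primers. `check_dimer(p, p)` is the self-dimer check used in
#' candidate screening.
#'
#' @param p,q Oligo sequences over `{A,C,G,T,W,S}`.
#' @param end_len 3'-end seed length (default 5).
#' @param match_len Minimum contiguous duplex length (default 8).
#' @return Logical flag.
#' @export
check_dimer <- function(p, q, end_len = 5L, match_len = 8L) {
  stopifnot(length(p) == 1L, length(q) == 1L)
  .check_oligo(c(p, q))
  for (pe in expand_degenerate(p))
    for (qe in expand_degenerate(q))
      if (.dimer_concrete(pe, qe, end_len, match_len)) return(TRUE)
  FALSE
}

.dimer_concrete <- function(p, q, end_len, match_len) {
  lp <- nchar(p); lq <- nchar(q)
  if (lp >= end_len) {
    seed <- revcomp(substr(p, lp - end_len + 1L, lp))
    if (grepl(seed, q, fixed = TRUE)) return(TRUE)
  }
  if (lq >= end_len) {
    seed <- revcomp(substr(q, lq - end_len + 1L, lq))
    if (grepl(seed, p, fixed = TRUE)) return(TRUE)
  }
  if (lp >= match_len && lq >= match_len) {
    rcq <- revcomp(q)
    kp <- substring(p, 1:(lp - match_len + 1L), match_len:lp)
    kq <- substring(rcq, 1:(lq - match_len + 1L), match_len:lq)
    if (any(kp %in% kq)) return(TRUE)
  }
  FALSE
}

#' Hairpin (self-hybridization) check
#'
#' Flags an oligo that contains two disjoint reverse-complementary segments
#' of at least `stem` nt separated by a loop of at least `loop` nt -- the
#' classic stem-loop geometry that self-primes or sequesters the primer.
#' Degenerate oligos are checked through all expansions.
#'
#' @param p Oligo over `{A,C,G,T,W,S}`.
#' @param stem Minimum stem length (default 4).
#' @param loop Minimum loop length (default 3).
#' @return Logical flag.
#' @export
check_hairpin <- function(p, stem = 4L, loop = 3L) {
  stopifnot(length(p) == 1L)
  .check_oligo(p)
  for (pe in expand_degenerate(p))
    if (.hairpin_concrete(pe, stem, loop)) return(TRUE)
  FALSE
}

.hairpin_concrete <- function(p, stem, loop) {
  n <- nchar(p)
  if (n < 2L * stem + loop) return(FALSE)
  k <- substring(p, 1:(n - stem + 1L), stem:n)
  rc <- revcomp(k)
  # stem1 at i, stem2 at j, loop between: j >= i + stem + loop
  fi <- match(k, rc)            # earliest i with rc(k[i]) == k[j]
  any(!is.na(fi) & seq_along(fi) - fi >= stem + loop)
}

## ---- vectorized catalogue screening ---------------------------------------
# Integer-coded k-mer matrices allow screening tens of thousands of
# candidates with a few hundred vectorized comparisons. Only concrete
# sequences take this path; W/S-degenerate candidates fall back to the
# scalar checks through their expansions.

.code_matrix <- function(seqs, L) {
  codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  m <- matrix(0L, nrow = length(seqs), ncol = L)
  for (i in seq_len(L)) m[, i] <- codes[substring(seqs, i, i)]
  m
}

.kmer_cols <- function(M, k, L) {
  # K[, i] = integer code of the k-mer starting at position i
  n <- nrow(M)
  K <- matrix(0L, nrow = n, ncol = L - k + 1L)
  for (i in seq_len(L - k + 1L)) {
    v <- 0L
    for (j in 0:(k - 1L)) v <- v * 4L + M[, i + j]
    K[, i] <- v
  }
  K
}

.rc_kmer_cols <- function(M, k, L) {
  # RC[, i] = integer code of revcomp of the k-mer starting at position i
  n <- nrow(M)
  C <- 3L - M
  RC <- matrix(0L, nrow = n, ncol = L - k + 1L)
  for (i in seq_len(L - k + 1L)) {
    v <- 0L
    for (j in (k - 1L):0) v <- v * 4L + C[, i + j]
    RC[, i] <- v
  }
  RC
}

# hairpin flags for equal-length concrete sequences
.screen_hairpin_len <- function(seqs, L, stem = 4L, loop = 3L) {
  n <- length(seqs)
  if (L < 2L * stem + loop) return(logical(n))
  M <- .code_matrix(seqs, L)
  K <- .kmer_cols(M, stem, L)
  RC <- .rc_kmer_cols(M, stem, L)
  flag <- logical(n)
  nw <- L - stem + 1L
  for (i in seq_len(nw)) {
    jmin <- i + stem + loop
    if (jmin > nw) break
    for (j in jmin:nw) flag <- flag | (K[, j] == RC[, i])
  }
  flag
}

# self-dimer flags for equal-length concrete sequences
.screen_selfdimer_len <- function(seqs, L, end_len = 5L, match_len = 8L) {
  n <- length(seqs)
  flag <- logical(n)
  M <- .code_matrix(seqs, L)
  if (L >= end_len) {
    K5 <- .kmer_cols(M, end_len, L)
    # revcomp of the 3'-terminal end_len-mer
    rc3 <- .rc_kmer_cols(M, end_len, L)[, L - end_len + 1L]
    for (i in seq_len(L - end_len + 1L)) flag <- flag | (K5[, i] == rc3)
  }
  if (L >= match_len) {
    K8 <- .kmer_cols(M, match_len, L)
    RC8 <- .rc_kmer_cols(M, match_len, L)
    nw <- L - match_len + 1L
    for (i in seq_len(nw))
      for (j in i:nw) flag <- flag | (K8[, j] == RC8[, i])
  }
  flag
}

# screening over a mixed-length candidate vector; returns TRUE where the
# candidate fails (hairpin or self-dimer)
.screen_fail <- function(seqs, end_len = 5L, match_len = 8L,
                         stem = 4L, loop = 3L) {
  fail <- logical(length(seqs))
  conc <- !grepl("[WS]", seqs)
  lens <- nchar(seqs)
  for (L in unique(lens[conc])) {
    idx <- which(conc & lens == L)
    fail[idx] <- .screen_hairpin_len(seqs[idx], L, stem, loop) |
      .screen_selfdimer_len(seqs[idx], L, end_len, match_len)
  }
  for (i in which(!conc)) {
    fail[i] <- check_hairpin(seqs[i], stem, loop) ||
      check_dimer(seqs[i], seqs[i], end_len, match_len)
  }
  fail
}
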