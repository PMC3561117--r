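# Small string-level oligo utilities shared across modules.

#' Reverse complement
#'
#' Vectorized reverse complement over the full IUPAC alphabet (delegates to
#' Biostrings). W and S are self-complementary, so W/S-degenerate primers
#' stay W/S-degenerate on the opposite strand.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  # Biostrings pays off on big batches; short vectors of primer-sized
  # strings are faster complemented in R
  if (length(x) > 200L || any(nchar(x) > 10000L))
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x))))
  comp <- chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Expand a degenerate oligo into its concrete sequences
#'
#' Every assignment of W -> {A,T} and S -> {G,C} positions; a primer with
#' `w` degenerate positions yields `2^w` concrete oligos (the primer pool
#' actually synthesized). A concrete input returns itself.
#'
#' @param p A single oligo over `{A,C,G,T,W,S}`.
#' @return Character vector of the `2^w` concrete expansions (sorted).
#' @examples
#' expand_degenerate("AWSG")  # AAGG AACG ATGG ATCG (sorted)
#' @export
expand_degenerate <- function(p) {
  stopifnot(is.character(p), length(p) == 1L)
  .check_oligo(p)
  if (!grepl("[WS]", p)) return(p)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  idx <- which(chars %in% c("W", "S"))
  if (length(idx) == 0L) return(p)
  alts <- lapply(chars[idx], function(c) if (c == "W") c("A", "T") else c("G", "C"))
  grid <- expand.grid(alts, stringsAsFactors = FALSE)
  out <- vapply(seq_len(nrow(grid)), function(i) {
    chars[idx] <- as.character(grid[i, ])
    paste(chars, collapse = "")
  }, character(1L))
  sort(unique(out))
}

# number of W/S positions
.n_degenerate <- function(x) nchar(x) - nchar(gsub("[WS]", "", x))

# IUPAC code for a set of concrete bases (and its inverse), backed by
# Biostrings' IUPAC_CODE_MAP.
.iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  code <- names(map)[match(key, map)]
  if (is.na(code)) stop("no IUPAC code for base set: ", key)
  code
}

.iupac_bases <- function(code) {
  map <- Biostrings::IUPAC_CODE_MAP
  b <- map[[code]]
  if (is.null(b)) stop("unknown IUPAC code: ", code)
  strsplit(b, "", fixed = TRUE)[[1L]]
}
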