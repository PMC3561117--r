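#' GC content of an oligonucleotide
#'
#' Fraction of positions that pair as G/C. The degenerate code S (G or C)
#' counts as G/C and W (A or T) as A/T, so W/S substitutions never change the
#' GC fraction -- the property that makes W/S-only degeneracy melting-
#' temperature neutral under a composition-based Tm formula.
#'
#' @param seq Character vector of oligo sequences over `{A,C,G,T,W,S}`.
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @examples
#' gc_content(c("ATAT", "GCGC", "ACGTS"))
#' @export
gc_content <- function(seq) {
  .check_oligo(seq)
  n <- nchar(seq)
  if (any(n == 0L)) stop("gc_content: empty sequence")
  ngc <- nchar(gsub("[^GCS]", "", seq))
  ngc / n
}

#' Oligonucleotide melting temperature
#'
#' Composition-based melting temperature for primer-length oligos:
#' `Tm = 64.9 + 41 * (nGC - 16.4) / N`, where `nGC` counts G, C and S
#' positions and `N` is the oligo length. A primer is said to *have* integer
#' target Tm `t` when `round(Tm) == t`. The formula depends only on length
#' and GC count, so every concrete expansion of a W/S-degenerate primer has
#' exactly the same Tm. A nearest-neighbour model would not have this
#' property (A<->T and G<->C swaps change stacking energies), which is why a
#' composition formula is mandatory here; the constant set is centralized in
#' this function so it can be swapped.
#'
#' @param seq Character vector over `{A,C,G,T,W,S}`, each at least 14 nt
#'   (the formula's validity regime for primer-sized oligos).
#' @return Numeric vector of melting temperatures in degrees centigrade.
#' @examples
#' melting_temperature(strrep("AT", 10))  # 20-mer, 0 GC
#' @export
melting_temperature <- function(seq) {
  .check_oligo(seq)
  n <- nchar(seq)
  if (any(n < 14L)) stop("melting_temperature: sequence shorter than 14 nt")
  ngc <- nchar(gsub("[^GCS]", "", seq))
  64.9 + 41 * (ngc - 16.4) / n
}

# Tm from GC count and length without materializing the string; the single
# source of the formula constants together with melting_temperature().
.tm_from_counts <- function(ngc, n) 64.9 + 41 * (ngc - 16.4) / n

.check_oligo <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L)
    stop("expected a non-empty character vector of oligo sequences")
  bad <- grepl("[^ACGTWS]", seq)
  if (any(bad))
    stop("invalid oligo character (allowed: A,C,G,T,W,S) in: ",
         seq[bad][1L])
  invisible(TRUE)
}
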