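# FASTA and configuration I/O, consensus/exceptions construction.

.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Read a FASTA file
#'
#' Minimal strict FASTA reader: records are returned in file order as an
#' uppercased named character vector; the record id is the first
#' whitespace-delimited token of the header. Wrapped and unwrapped sequence
#' lines are accepted. Malformed headers or non-IUPAC characters raise a
#' parse error naming the offending line; an empty file yields an empty
#' vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @seealso [write_fasta()], [gene_set()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("read_fasta: line ", lineno[1L], ": expected '>' header, got: ",
         substr(lines[1L], 1L, 30L))
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[is_hdr])
  if (any(ids == ">" | nchar(sub("^>", "", lines[is_hdr])) == 0L)) {
    bad <- lineno[is_hdr][which(nchar(sub("^>\\s*", "", lines[is_hdr])) == 0L)[1L]]
    stop("read_fasta: line ", bad, ": empty FASTA header")
  }
  seq_lines <- toupper(lines)
  bad_chr <- !is_hdr & grepl(paste0("[^", .IUPAC_CHARS, "]"), seq_lines)
  if (any(bad_chr))
    stop("read_fasta: line ", lineno[bad_chr][1L],
         ": non-IUPAC character in sequence")
  rec <- cumsum(is_hdr)
  seqs <- vapply(split(seq_lines[!is_hdr], rec[!is_hdr]),
                 paste, character(1L), collapse = "")
  # records with no sequence lines are legal (empty sequence)
  out <- stats::setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (names become headers).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Target gene set with optional collated SNPs
#'
#' Pairs consensus sequences with optional *exceptions* sequences: for each
#' gene, the exceptions sequence has the same length as the consensus and
#' encodes all collated SNPs as IUPAC ambiguity codes (the consensus base is
#' always a member of the ambiguity set). Genes without SNP information may
#' omit the exceptions entry.
#'
#' @param consensus Named character vector of consensus sequences over
#'   `{A,C,G,T,N}`.
#' @param exceptions Optional named character vector of IUPAC exceptions
#'   sequences; names must be a subset of the consensus names.
#' @return An object of class `gene_set`: list with `id`, `consensus`,
#'   `exceptions` (NA where absent) and `length`.
#' @export
gene_set <- function(consensus, exceptions = NULL) {
  stopifnot(is.character(consensus), !is.null(names(consensus)))
  consensus <- toupper(consensus)
  if (any(grepl("[^ACGTN]", consensus)))
    stop("gene_set: consensus sequences must be over {A,C,G,T,N}")
  if (anyDuplicated(names(consensus)))
    stop("gene_set: duplicated gene ids")
  exc <- rep(NA_character_, length(consensus))
  names(exc) <- names(consensus)
  if (!is.null(exceptions)) {
    exceptions <- toupper(exceptions)
    unknown <- setdiff(names(exceptions), names(consensus))
    if (length(unknown))
      stop("gene_set: exceptions for unknown gene(s): ",
           paste(unknown, collapse = ", "))
    for (id in names(exceptions)) {
      e <- exceptions[[id]]; s <- consensus[[id]]
      if (nchar(e) != nchar(s))
        stop("gene_set: exceptions length mismatch for gene ", id)
      if (grepl(paste0("[^", .IUPAC_CHARS, "]"), e))
        stop("gene_set: non-IUPAC character in exceptions of gene ", id)
      sc <- strsplit(s, "")[[1L]]; ec <- strsplit(e, "")[[1L]]
      diff <- which(sc != ec & sc != "N")
      for (j in diff) {
        if (!(sc[j] %in% .iupac_bases(ec[j])))
          stop("gene_set: gene ", id, " position ", j,
               ": exception code ", ec[j],
               " does not contain consensus base ", sc[j])
      }
      exc[[id]] <- e
    }
  }
  structure(list(id = names(consensus),
                 consensus = unname(consensus),
                 exceptions = unname(exc),
                 length = unname(nchar(consensus))),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", length(x$id), "gene(s),",
      sum(x$length), "bp total,",
      sum(!is.na(x$exceptions)), "with SNP exceptions\n")
  invisible(x)
}

#' Build consensus and exceptions sequences from per-gene variants
#'
#' Collapses pre-aligned, ungapped variant sequences of each gene into a
#' consensus (column-wise majority base, ties broken alphabetically
#' A < C < G < T) and an exceptions sequence (the IUPAC code of the set of
#' bases observed in the column). Variants of a gene must all have the same
#' length; alignment is out of scope.
#'
#' @param variants Named list; each element is a character vector of
#'   equal-length variant sequences for one gene.
#' @return A [gene_set()] whose exceptions encode all observed SNPs.
#' @examples
#' generate_exceptions(list(g1 = c("AAGT", "ATGT", "ATGT")))
#' @export
generate_exceptions <- function(variants) {
  stopifnot(is.list(variants), !is.null(names(variants)))
  cons <- exc <- character(length(variants))
  for (k in seq_along(variants)) {
    v <- toupper(variants[[k]])
    if (length(v) < 1L) stop("generate_exceptions: gene ",
                             names(variants)[k], " has no variants")
    if (length(unique(nchar(v))) != 1L)
      stop("generate_exceptions: unequal variant lengths for gene ",
           names(variants)[k])
    if (any(grepl("[^ACGT]", v)))
      stop("generate_exceptions: variants must be over {A,C,G,T} (gene ",
           names(variants)[k], ")")
    m <- do.call(rbind, strsplit(v, "", fixed = TRUE))
    cols <- apply(m, 2L, function(col) {
      tab <- table(factor(col, levels = c("A", "C", "G", "T")))
      maj <- names(tab)[which.max(tab)]   # which.max takes first => A<C<G<T
      c(maj, .iupac_code_for(col))
    })
    cons[k] <- paste(cols[1L, ], collapse = "")
    exc[k] <- paste(cols[2L, ], collapse = "")
  }
  names(cons) <- names(exc) <- names(variants)
  gene_set(cons, exc)
}

## ---- configuration ---------------------------------------------------------

# canonical fields, defaults, and types
.CFG_DEFAULTS <- list(
  background_path = NA_character_,
  max_degeneracy = 3L,
  tm_min = 50L, tm_max = 60L,
  amplicon_min = 50L, amplicon_max = 250L,
  initial_overlap = 0L,
  n_iterations = 10000L,
  max_gap = 10L,
  save_interim = FALSE,
  verbose = FALSE,
  cost_tolerance = 0,
  output_path = "primertile_results.out",
  restart = FALSE,
  prob_remove_redundant = 0,
  early_proportion = 0,
  weight_greedy = TRUE,
  remove_nonreusable = FALSE,
  heating = 0.2,
  primer_len_min = 18L, primer_len_max = 27L,
  max_redundancy = 10L,
  rng_seed = NA_integer_,
  heating_mode = "boltzmann",
  reuse_costing = TRUE
)

.CFG_INT <- c("max_degeneracy", "tm_min", "tm_max", "amplicon_min",
              "amplicon_max", "initial_overlap", "n_iterations", "max_gap",
              "primer_len_min", "primer_len_max", "max_redundancy", "rng_seed")
.CFG_FLAG <- c("save_interim", "verbose", "restart", "weight_greedy",
               "remove_nonreusable", "reuse_costing")
.CFG_NUM <- c("cost_tolerance", "prob_remove_redundant", "early_proportion",
              "heating")

# descriptive key aliases (normalized: lowercase, single spaces, quotes
# stripped) as they appear in a key/value configuration file
.CFG_ALIASES <- c(
  "genome file for blast searching" = "background_path",
  "background file"                 = "background_path",
  "max degeneracy (base pairs)"     = "max_degeneracy",
  "minumum melting temperature (centigrade)" = "tm_min",
  "minimum melting temperature (centigrade)" = "tm_min",
  "maximum melting temperature (centigrade)" = "tm_max",
  "minimum amplicon length (base pairs)" = "amplicon_min",
  "maximum amplicon length (base pairs)" = "amplicon_max",
  "initial overlap (base pairs)"    = "initial_overlap",
  "number of optimisations"         = "n_iterations",
  "number of optimizations"         = "n_iterations",
  "maximum gap between sequences (base pairs)" = "max_gap",
  "save interim optimizations?"     = "save_interim",
  "verbose output?"                 = "verbose",
  "cost tolerance"                  = "cost_tolerance",
  "output file name"                = "output_path",
  "restart from previous run?"      = "restart",
  "probability of removing redundant primer pairs" = "prob_remove_redundant",
  "proportion of iterations to be considered as early" = "early_proportion",
  "weight greedy methods according to optimization?" = "weight_greedy",
  "remove non-reusable primers from initial design?" = "remove_nonreusable",
  "proportion of failed weight check proposals to accept (heating)" = "heating",
  "minimum primer length (base pairs)" = "primer_len_min",
  "maximum primer length (base pairs)" = "primer_len_max",
  "maximum redundancy"              = "max_redundancy",
  "rng seed"                        = "rng_seed",
  "heating mode"                    = "heating_mode"
)

#' Construct a validated run configuration
#'
#' All knobs of the design/optimization pipeline with their defaults:
#' melting temperature range 50--60 C, amplicon length 50--250 bp, at most 3
#' degenerate (W/S) bases per primer, at most 10-fold redundancy, 10000 MCMC
#' iterations, heating H = 0.2, primer length 18--27 nt. `heating_mode`
#' selects the uphill-acceptance rule: `"boltzmann"` (accept with probability
#' `min(1, exp(-deltaS * H))`, the default) or `"fraction"` (accept a fixed
#' fraction H of uphill proposals). `reuse_costing = FALSE` charges every
#' primer use separately instead of paying each distinct primer once (used
#' to quantify the saving from reuse).
#'
#' @param ... Named overrides of any configuration field.
#' @return An object of class `primer_config` (a validated named list).
#' @export
primer_config <- function(...) {
  over <- list(...)
  cfg <- .CFG_DEFAULTS
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("primer_config: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (f in .CFG_INT) cfg[[f]] <- as.integer(cfg[[f]])
  for (f in .CFG_NUM) cfg[[f]] <- as.numeric(cfg[[f]])
  for (f in .CFG_FLAG) cfg[[f]] <- as.logical(cfg[[f]])
  validate_config(cfg)
  structure(cfg, class = "primer_config")
}

#' Validate configuration invariants
#'
#' @param cfg A configuration list.
#' @return Invisibly `TRUE`; otherwise a validation error listing every
#'   violated field.
#' @export
validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  chk(cfg$tm_min <= cfg$tm_max, "tm_min > tm_max")
  chk(cfg$primer_len_min <= cfg$primer_len_max,
      "primer_len_min > primer_len_max")
  chk(cfg$primer_len_min >= 14L, "primer_len_min < 14 (Tm formula regime)")
  chk(2L * cfg$primer_len_min <= cfg$amplicon_min,
      "amplicon_min < 2 * primer_len_min")
  chk(cfg$amplicon_min <= cfg$amplicon_max, "amplicon_min > amplicon_max")
  for (f in c("prob_remove_redundant", "early_proportion"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "outside [0,1]"))
  chk(cfg$heating >= 0, "heating < 0")
  chk(cfg$heating_mode != "fraction" ||
        (cfg$heating >= 0 && cfg$heating <= 1),
      "heating outside [0,1] under heating_mode = 'fraction'")
  chk(cfg$n_iterations >= 1L, "n_iterations < 1")
  chk(cfg$max_degeneracy >= 0L, "max_degeneracy < 0")
  chk(cfg$max_redundancy >= 1L, "max_redundancy < 1")
  chk(cfg$heating_mode %in% c("boltzmann", "fraction"),
      "heating_mode not one of 'boltzmann', 'fraction'")
  if (length(bad))
    stop("invalid configuration: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

#' @export
print.primer_config <- function(x, ...) {
  cat("primer_config:\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Parse a plain-text configuration file
#'
#' One `key<TAB or =>value` pair per line (when neither separator is
#' present, the last whitespace-delimited token is taken as the value);
#' `#` starts a comment; keys are matched case-insensitively after
#' whitespace normalization, and both the descriptive names (e.g.
#' `"Max degeneracy (base pairs)"`) and the short field names (e.g.
#' `max_degeneracy`) are accepted. Unknown keys are rejected; missing keys
#' take their defaults; flags parse 0/1.
#'
#' @param path Path to the configuration file.
#' @return A validated [primer_config()] object.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("parse_config: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    if (grepl("\t", ln, fixed = TRUE)) {
      parts <- strsplit(ln, "\t+")[[1L]]
      key <- parts[1L]; val <- paste(parts[-1L], collapse = " ")
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- sub("=.*$", "", ln); val <- sub("^[^=]*=", "", ln)
    } else {
      toks <- strsplit(ln, "\\s+")[[1L]]
      if (length(toks) < 2L)
        stop("parse_config: cannot split key/value in line: ", ln)
      key <- paste(toks[-length(toks)], collapse = " ")
      val <- toks[length(toks)]
    }
    key_norm <- tolower(gsub("\\s+", " ", trimws(key)))
    key_norm <- gsub("[`']", "", key_norm)
    field <- if (key_norm %in% names(.CFG_ALIASES)) {
      .CFG_ALIASES[[key_norm]]
    } else {
      cand <- gsub(" ", "_", key_norm)
      if (!cand %in% names(.CFG_DEFAULTS))
        stop("parse_config: unknown configuration key: ", trimws(key))
      cand
    }
    val <- trimws(val)
    over[[field]] <-
      if (field %in% .CFG_FLAG) {
        if (!val %in% c("0", "1")) stop("parse_config: flag ", field,
                                        " must be 0 or 1, got: ", val)
        val == "1"
      } else if (field %in% .CFG_INT) as.integer(val)
      else if (field %in% .CFG_NUM) as.numeric(val)
      else val
  }
  do.call(primer_config, over)
}
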