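#' Decode Phred quality strings to integer scores
#'
#' @param qual character vector of FASTQ quality strings.
#' @param offset ASCII offset of the encoding (33 for Phred+33, 64 for the
#'   legacy Phred+64 dialect).
#' @return a list of integer vectors, one per input string.
#' @examples
#' phred_to_int("I!")[[1]] # 40 0
#' @export
phred_to_int <- function(qual, offset = 33L) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer(0))
    utf8ToInt(q) - as.integer(offset)
  })
}

#' Encode integer quality scores as a Phred string
#'
#' @param scores integer vector of per-base quality scores.
#' @param offset ASCII offset (default Phred+33).
#' @return a single character string.
#' @export
int_to_phred <- function(scores, offset = 33L) {
  if (length(scores) == 0) return("")
  intToUtf8(as.integer(scores) + as.integer(offset))
}

#' Round a percentage half away from zero
#'
#' Integer rounding used for use-versus-availability tables: 12.5 rounds to
#' 13, -12.5 to -13 (base `round()` would give 12 under banker's rounding).
#'
#' @param x numeric vector.
#' @return integer vector.
#' @examples
#' percent_round(100 * 45 / 360) # 13
#' @export
percent_round <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Normalize a taxon label for matching
#'
#' Lowercases and collapses internal whitespace; survey lists and checklists
#' are hand-curated, so matching is case- and spacing-insensitive.
#'
#' @param x character vector of taxon labels.
#' @return normalized character vector.
#' @export
normalize_label <- function(x) {
  tolower(trimws(gsub("\\s+", " ", x)))
}

# First whitespace-delimited token of a taxon label (its genus for binomials).
genus_token <- function(x) {
  sub("\\s.*$", "", trimws(x))
}

# Reverse-complement for plain character vectors of DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
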