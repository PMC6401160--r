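# shared low-level helpers (sequence arithmetic, rounding, validation)

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over character strings (alphabet ACGTN).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGTA"))
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample from a vector even when it has length 1 (avoids sample()'s
# scalar expansion)
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Per-position mismatch indicator between two equal-length strings.
mismatch_vector <- function(a, b) {
  charToRaw(a) != charToRaw(b)
}

# 0-based half-open substring of a 1-based R string: bases [start, end).
substr0 <- function(s, start, end) {
  substr(s, start + 1L, end)
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up to two decimals,
#' the convention used throughout tissue-sharing and overlap summaries.
#'
#' @param numerator,denominator non-negative counts; `denominator > 0`.
#' @return numeric percentage rounded to 2 decimals.
#' @export
#' @examples
#' overlap_percent(674, 1196)
overlap_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    abort("`denominator` must be > 0.")
  }
  round_half_up(100 * numerator / denominator, 2L)
}

# round half away from zero at `digits` decimals (base round() is banker's)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# coerce a genome given as DNAStringSet / named character / sim_genome
# into a named character vector of chromosome strings
genome_strings <- function(genome) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("a character genome must be a named vector of chromosome strings")
    }
    return(genome)
  }
  abort("`genome` must be a DNAStringSet, named character vector or sim_genome")
}

assert_reads_tbl <- function(reads, arg = "reads") {
  if (!is.data.frame(reads) ||
      !all(c("read_id", "seq", "qual") %in% names(reads))) {
    abort(sprintf(
      "`%s` must be a data frame with columns read_id, seq and qual", arg
    ))
  }
  invisible(reads)
}

# decode Sanger Phred+33 quality string to integer scores
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

phred_encode <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}
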