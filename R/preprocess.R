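#' Quality-trim reads from the 3' end
#'
#' Applies a trailing-quality trim: each read is cut back to its last base
#' with Phred quality at or above `phred_cutoff`, and reads shorter than
#' `min_len` after trimming are dropped. The default cutoff of 30 is the
#' usual pre-alignment filter for junction discovery; `min_len` defaults to
#' twice the anchor length (40) so that head and tail anchors remain
#' extractable downstream. Trimming is idempotent: a second pass changes
#' nothing.
#'
#' @param reads read tibble (`read_id`, `seq`, `qual`, optionally `tissue`).
#' @param phred_cutoff minimum retained 3'-terminal base quality.
#' @param min_len minimum read length after trimming.
#' @param adapter optional adapter sequence; when supplied, each read is
#'   clipped at the first position where its suffix matches a prefix (>= 5
#'   nt) of the adapter, before quality trimming. Synthetic reads carry no
#'   adapters, so this is off by default.
#' @return tibble of surviving reads (same columns, trimmed `seq`/`qual`)
#'   with a `trim_summary` attribute: a one-row tibble of `n_in`,
#'   `n_trimmed`, `n_dropped`, `n_out`, `bases_removed`. Retrieve it with
#'   [trim_summary()].
#' @export
#' @examples
#' reads <- tibble::tibble(read_id = "r1",
#'                         seq = strrep("ACGT", 25),
#'                         qual = strrep("I", 100))
#' nrow(quality_trim(reads))
quality_trim <- function(reads, phred_cutoff = 30L, min_len = 40L,
                         adapter = NULL) {
  assert_reads_tbl(reads)
  n_in <- nrow(reads)
  if (!n_in) {
    out <- reads
    attr(out, "trim_summary") <- tibble(
      n_in = 0L, n_trimmed = 0L, n_dropped = 0L, n_out = 0L,
      bases_removed = 0L
    )
    return(out)
  }
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("malformed reads: sequence and quality lengths differ")
  }

  seqs <- reads$seq
  quals <- reads$qual
  if (!is.null(adapter)) {
    clip_at <- adapter_clip_positions(seqs, adapter)
    seqs <- substr(seqs, 1L, clip_at)
    quals <- substr(quals, 1L, clip_at)
  }

  scores <- phred_decode(quals)
  keep_len <- vapply(scores, function(q) {
    ok <- which(q >= phred_cutoff)
    if (length(ok)) max(ok) else 0L
  }, integer(1))

  trimmed <- reads
  trimmed$seq <- substr(seqs, 1L, keep_len)
  trimmed$qual <- substr(quals, 1L, keep_len)

  survive <- keep_len >= min_len
  out <- trimmed[survive, , drop = FALSE]
  attr(out, "trim_summary") <- tibble(
    n_in = n_in,
    n_trimmed = sum(keep_len < nchar(reads$seq)),
    n_dropped = sum(!survive),
    n_out = sum(survive),
    bases_removed = sum(nchar(reads$seq) - keep_len)
  )
  out
}

#' @param trimmed the result of [quality_trim()].
#' @rdname quality_trim
#' @export
trim_summary <- function(trimmed) {
  attr(trimmed, "trim_summary")
}

# position (1-based, inclusive) at which to cut each read so that any
# 3'-terminal match to an adapter prefix of >= 5 nt is removed
adapter_clip_positions <- function(seqs, adapter) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- regexpr(adapter, s, fixed = TRUE)[1]
    if (hit > 0L) return(hit - 1L)
    from <- min(n - 1L, nchar(adapter) - 1L)
    if (from >= 5L) {
      for (plen in seq(from, 5L)) {
        if (substr(s, n - plen + 1L, n) == substr(adapter, 1L, plen)) {
          return(n - plen)
        }
      }
    }
    n
  }, integer(1), USE.NAMES = FALSE)
}
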