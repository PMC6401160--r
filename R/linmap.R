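# Contiguous (end-to-end) alignment. The job of this module is binary:
# decide whether a read is linearly explained by the genome (<= max_mismatch
# substitutions somewhere, either strand) or not; only unmapped reads feed
# back-splice detection. An ungapped k-mer-seeded Hamming aligner is
# sufficient for that contract and keeps the mismatch semantics explicit.

#' Build a k-mer genome index
#'
#' Indexes every non-ambiguous k-mer of every chromosome on both strands.
#' Reverse-strand k-mers are stored under their reverse-complement sequence
#' with forward coordinates and a `-` strand flag, so all lookups are
#' against forward chromosome strings.
#'
#' @param genome `DNAStringSet`, named character vector or `sim_genome`.
#' @param k seed length (default 20, the anchor length of the back-splice
#'   caller, which requires `k == anchor_len`).
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome, k = 20L) {
  gs <- genome_strings(genome)
  if (!length(gs) || any(!nzchar(gs))) abort("`genome` must be non-empty")
  k <- as.integer(k)
  if (k > min(nchar(gs))) {
    abort(sprintf("k (%d) exceeds the shortest chromosome (%d bp)",
                  k, min(nchar(gs))))
  }
  pieces <- lapply(names(gs), function(cn) {
    s <- gs[[cn]]
    n <- nchar(s)
    starts <- seq_len(n - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    rc <- substring(revcomp(s), starts, starts + k - 1L)
    data.table::data.table(
      kmer = c(fwd, rc),
      chrom = cn,
      pos = c(starts - 1L, n - starts - k + 1L),
      strand = rep(c("+", "-"), each = length(starts))
    )
  })
  dt <- data.table::rbindlist(pieces)
  dt <- dt[!grepl("[^ACGT]", dt$kmer), ]
  data.table::setkeyv(dt, "kmer")
  structure(
    list(k = k, seqs = gs, chrom_lengths = setNames(nchar(gs), names(gs)),
         dt = dt),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> k=%d, %d chromosome(s), %d k-mer entries\n",
              x$k, length(x$seqs), nrow(x$dt)))
  invisible(x)
}

#' Query exact k-mer occurrences
#'
#' @param index a [build_index()] result.
#' @param kmers character vector of length-`k` sequences.
#' @return tibble `kmer`, `chrom`, `pos` (0-based forward start), `strand`;
#'   zero rows for absent k-mers.
#' @export
query_kmers <- function(index, kmers) {
  hits <- index$dt[data.table::data.table(kmer = kmers), on = "kmer",
                   nomatch = NULL]
  as_tibble(hits)
}

#' Align reads end-to-end against the genome
#'
#' Reports every locus (both strands) where the entire read aligns ungapped
#' with at most `max_mismatch` substitutions. Candidate loci are seeded by
#' exact k-mer matches at three read offsets (head, centre, tail); with
#' disjoint seeds — guaranteed for reads of length >= 3k — a read harbouring
#' at most `max_mismatch < 3` substitutions always retains one clean seed,
#' so no qualifying locus is missed. An empty result means the read is not
#' contiguously explained and is forwarded to back-splice detection.
#'
#' @param reads read tibble.
#' @param index a [build_index()] result.
#' @param max_mismatch maximum substitutions for a reported hit (default 2).
#' @return tibble of hits: `read_id`, `chrom`, `pos` (0-based alignment
#'   start on the forward strand), `strand`, `mismatches`, `is_unique`
#'   (best score strictly better than any other locus for that read).
#' @export
align_end_to_end <- function(reads, index, max_mismatch = 2L) {
  assert_reads_tbl(reads)
  empty <- tibble(read_id = character(0), chrom = character(0),
                  pos = integer(0), strand = character(0),
                  mismatches = integer(0), is_unique = logical(0))
  if (!nrow(reads)) return(empty)
  k <- index$k
  lens <- nchar(reads$seq)
  if (any(lens < k)) abort("all reads must be at least k bases long")

  # seed table: (read row, seed offset, kmer)
  seed_tbl <- lapply(c("head", "mid", "tail"), function(which_seed) {
    off <- switch(which_seed,
                  head = rep(0L, nrow(reads)),
                  mid = (lens - k) %/% 2L,
                  tail = lens - k)
    data.table::data.table(
      ridx = seq_len(nrow(reads)), off = off,
      kmer = substr(reads$seq, off + 1L, off + k)
    )
  })
  seed_tbl <- unique(data.table::rbindlist(seed_tbl))

  hits <- index$dt[seed_tbl, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(hits)) return(empty)

  # convert seed position to full-read alignment start (forward coords)
  L <- lens[hits$ridx]
  start <- ifelse(hits$strand == "+",
                  hits$pos - hits$off,
                  hits$pos - (L - k - hits$off))
  cand <- unique(data.table::data.table(
    ridx = hits$ridx, chrom = hits$chrom, start = start,
    strand = hits$strand, L = L
  ))
  cand <- cand[cand$start >= 0L &
                 cand$start + cand$L <= index$chrom_lengths[cand$chrom], ]
  if (!nrow(cand)) return(empty)

  # verify: Hamming distance of the (oriented) read against the locus
  qseq <- reads$seq[cand$ridx]
  flip <- cand$strand == "-"
  if (any(flip)) qseq[flip] <- revcomp(qseq[flip])
  gsub_ <- substr(vapply(cand$chrom, function(cn) index$seqs[[cn]],
                         character(1), USE.NAMES = FALSE),
                  cand$start + 1L, cand$start + cand$L)
  mm <- mapply(hamming, qseq, gsub_, USE.NAMES = FALSE)

  out <- tibble(
    read_id = reads$read_id[cand$ridx],
    chrom = cand$chrom, pos = cand$start, strand = cand$strand,
    mismatches = as.integer(mm)
  ) %>%
    filter(.data$mismatches <= max_mismatch)
  if (!nrow(out)) return(empty)
  out %>%
    group_by(.data$read_id) %>%
    mutate(is_unique = .data$mismatches == min(.data$mismatches) &
             sum(.data$mismatches == min(.data$mismatches)) == 1L) %>%
    ungroup() %>%
    arrange(.data$read_id, .data$chrom, .data$pos, .data$strand)
}

#' Partition reads into contiguously mapped and unmapped sets
#'
#' Reads with at least one end-to-end alignment are discarded from junction
#' discovery (they are linearly explained); the remainder is the unmapped
#' set handed to [detect_backsplice()].
#'
#' @inheritParams align_end_to_end
#' @return list with `mapped` and `unmapped` read tibbles (a disjoint,
#'   exhaustive partition of `reads`) and `summary`, a per-tissue tibble of
#'   `n_reads`, `n_mapped`, `mapped_frac`.
#' @export
partition_reads <- function(reads, index, max_mismatch = 2L) {
  assert_reads_tbl(reads)
  hits <- align_end_to_end(reads, index, max_mismatch = max_mismatch)
  mapped_ids <- unique(hits$read_id)
  is_mapped <- reads$read_id %in% mapped_ids
  tis <- if ("tissue" %in% names(reads)) reads$tissue else "all"
  summary <- tibble(tissue = tis, mapped = is_mapped) %>%
    group_by(.data$tissue) %>%
    summarise(n_reads = n(), n_mapped = sum(.data$mapped),
              mapped_frac = mean(.data$mapped), .groups = "drop")
  list(
    mapped = reads[is_mapped, , drop = FALSE],
    unmapped = reads[!is_mapped, , drop = FALSE],
    summary = summary
  )
}

#' Write a minimal SAM file of end-to-end hits
#'
#' A convenience writer for inspection: QNAME/FLAG/RNAME/POS/MAPQ/CIGAR with
#' a full-length match CIGAR. Not intended as a full SAM implementation.
#'
#' @param hits tibble from [align_end_to_end()].
#' @param reads the read tibble the hits refer to.
#' @param index the index used (for header lengths).
#' @param path output path.
#' @export
write_sam_minimal <- function(hits, reads, index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(index$chrom_lengths),
            index$chrom_lengths)
  ), con)
  if (nrow(hits)) {
    rd <- reads[match(hits$read_id, reads$read_id), ]
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
      hits$read_id, ifelse(hits$strand == "-", 16L, 0L), hits$chrom,
      hits$pos + 1L, ifelse(hits$is_unique, 60L, 0L), nchar(rd$seq),
      rd$seq, rd$qual
    ), con)
  }
  invisible(path)
}
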