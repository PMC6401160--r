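# Back-splice junction discovery from unmapped reads.
#
# A read crossing a back-splice junction is, in forward-genome terms, a
# suffix of the region ending at the donor breakpoint followed by a prefix
# of the region starting at the acceptor breakpoint — its two 20-nt terminal
# anchors therefore align in reversed genomic order (head downstream of
# tail). Candidate breakpoints are enumerated over every split offset of the
# read interior under the total mismatch budget, and the breakpoint whose
# genomic flanks carry the canonical splice signal is selected: on the plus
# strand AG immediately before the acceptor start and GT immediately after
# the donor end; on the minus strand the forward genome shows AC/CT at the
# same positions. Junctions supported by fewer than `min_support` distinct
# reads are dropped.

#' Extract terminal anchors from reads
#'
#' @param reads read tibble.
#' @param anchor_len anchor length (default 20).
#' @return tibble `read_id`, `head`, `tail` for reads long enough to carry
#'   two anchors; the number of rejected short reads is attached as
#'   attribute `n_rejected`.
#' @export
extract_anchors <- function(reads, anchor_len = 20L) {
  assert_reads_tbl(reads)
  lens <- nchar(reads$seq)
  ok <- lens >= 2L * anchor_len
  out <- tibble(
    read_id = reads$read_id[ok],
    head = substr(reads$seq[ok], 1L, anchor_len),
    tail = substr(reads$seq[ok], lens[ok] - anchor_len + 1L, lens[ok])
  )
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Pair head/tail anchor hits in reversed genomic order
#'
#' Keeps read-wise anchor pairs on one chromosome and strand, both uniquely
#' aligned, where the head anchor lies downstream of the tail anchor on the
#' transcribed strand — the reversed order diagnostic of back-splicing —
#' and the implied junction extent falls within `[min_span, max_span]`.
#'
#' @param head_hits,tail_hits hit tibbles (`read_id`, `chrom`, `pos`,
#'   `strand`, `is_unique`) for the head and tail anchors.
#' @param min_span,max_span admissible junction extent in bases.
#' @param read_len,anchor_len used to convert anchor separation into
#'   junction extent (`|head - tail| + read_len - anchor_len`).
#' @return tibble of retained pairs: `read_id`, `chrom`, `strand`,
#'   `head_pos`, `tail_pos`, `span`.
#' @export
pair_anchors <- function(head_hits, tail_hits, min_span = 50L,
                         max_span = 100000L, read_len = 101L,
                         anchor_len = 20L) {
  pairs <- inner_join(
    head_hits %>% filter(.data$is_unique) %>%
      select("read_id", "chrom", "strand", head_pos = "pos"),
    tail_hits %>% filter(.data$is_unique) %>%
      select("read_id", "chrom", "strand", tail_pos = "pos"),
    by = c("read_id", "chrom", "strand")
  ) %>%
    mutate(
      delta = ifelse(.data$strand == "-",
                     .data$tail_pos - .data$head_pos,
                     .data$head_pos - .data$tail_pos),
      span = .data$delta + read_len - anchor_len
    ) %>%
    filter(.data$delta > 0L, .data$span >= min_span,
           .data$span <= max_span) %>%
    select("read_id", "chrom", "strand", "head_pos", "tail_pos", "span")
  pairs
}

# per-position mismatch indicator of `seq` laid ungapped on the forward
# chromosome starting at 0-based g0; out-of-bounds positions count as
# mismatches
frame_mismatch <- function(seq, chrom_seq, g0) {
  L <- nchar(seq)
  clen <- nchar(chrom_seq)
  if (g0 >= 0L && g0 + L <= clen) {
    return(mismatch_vector(seq, substr0(chrom_seq, g0, g0 + L)))
  }
  out <- rep(TRUE, L)
  lo <- max(0L, -g0)           # first in-bounds read index (0-based)
  hi <- min(L, clen - g0)      # one past last in-bounds read index
  if (hi > lo) {
    out[(lo + 1L):hi] <- mismatch_vector(
      substr(seq, lo + 1L, hi),
      substr0(chrom_seq, g0 + lo, g0 + hi)
    )
  }
  out
}

# splice-signal strand at a candidate junction, or NA when neither strand
# shows the canonical signal
signal_strand <- function(chrom_seq, start, end) {
  if (start < 2L || end + 2L > nchar(chrom_seq)) return(NA_character_)
  left <- substr0(chrom_seq, start - 2L, start)
  right <- substr0(chrom_seq, end, end + 2L)
  if (left == "AG" && right == "GT") return("+")
  if (left == "AC" && right == "CT") return("-")
  NA_character_
}

#' Extend an anchor pair and call a breakpoint
#'
#' Given a read whose head anchor aligned at `head_pos` and tail anchor at
#' `tail_pos` (reversed order, forward coordinates), enumerates every split
#' offset `b` of the read (`anchor_len <= b <= read_len - anchor_len`,
#' donor-side length) consistent with a total of at most `max_mismatch`
#' substitutions, and selects among feasible offsets the one whose genomic
#' flanks carry the canonical splice signal. Ties are resolved by fewest
#' mismatches, then the leftmost breakpoint. The junction strand is the
#' strand exhibiting the GT/AG signal.
#'
#' @param seq read sequence, oriented so that it matches the forward genome
#'   (the detector tries both the read and its reverse complement).
#' @param chrom_seq forward chromosome string.
#' @param head_pos,tail_pos 0-based anchor alignment starts.
#' @param anchor_len anchor length.
#' @param max_mismatch total substitution budget across both sides.
#' @return a tibble (`start`, `end`, `strand`, `split`, `mismatches`) with
#'   one row on success and zero rows on failure; failures carry the
#'   attribute `reason` (`"mismatch_overflow"` or `"no_signal"`).
#' @export
call_breakpoint <- function(seq, chrom_seq, head_pos, tail_pos,
                            anchor_len = 20L, max_mismatch = 2L) {
  L <- nchar(seq)
  A <- anchor_len
  g0 <- tail_pos + A - L  # acceptor-frame origin
  d <- frame_mismatch(seq, chrom_seq, head_pos)
  a <- frame_mismatch(seq, chrom_seq, g0)
  pre <- c(0L, cumsum(d))        # pre[b+1] = mismatches in donor part 1..b
  suf <- c(rev(cumsum(rev(a))), 0L)  # suf[b+1] = mismatches in part b+1..L
  bs <- seq(A, L - A)
  m <- pre[bs + 1L] + suf[bs + 1L]
  feas <- which(m <= max_mismatch)
  if (!length(feas)) {
    return(breakpoint_failure("mismatch_overflow"))
  }
  ord <- feas[order(m[feas], bs[feas])]
  for (i in ord) {
    b <- bs[i]
    start <- g0 + b
    end <- head_pos + b
    strand <- signal_strand(chrom_seq, start, end)
    if (!is.na(strand)) {
      return(tibble(start = start, end = end, strand = strand,
                    split = b, mismatches = as.integer(m[i])))
    }
  }
  breakpoint_failure("no_signal")
}

breakpoint_failure <- function(reason) {
  out <- tibble(start = integer(0), end = integer(0), strand = character(0),
                split = integer(0), mismatches = integer(0))
  attr(out, "reason") <- reason
  out
}

#' Aggregate per-read junction candidates
#'
#' Groups candidates by exact coordinates and strand, counts distinct
#' supporting reads, and drops junctions below `min_support`. When the
#' candidates carry a `tissue` column the support filter is applied per
#' tissue by default (each tissue's library must reach `min_support` on its
#' own, mirroring per-library detection); `pooled = TRUE` applies it to the
#' summed support instead.
#'
#' @param candidates tibble with `read_id`, `chrom`, `start`, `end`,
#'   `strand` (and optionally `tissue`).
#' @param min_support minimum distinct supporting reads (default 2).
#' @param pooled apply `min_support` to the tissue-pooled support.
#' @return junction tibble sorted by (chrom, start, end): `chrom`, `start`,
#'   `end`, `strand`, `splice_signal`, `support`, `name`; per-tissue support
#'   is attached as attribute `tissue_support` (long tibble) when a tissue
#'   column was present.
#' @export
aggregate_junctions <- function(candidates, min_support = 2L,
                                pooled = FALSE) {
  key <- c("chrom", "start", "end", "strand")
  if (!nrow(candidates)) {
    return(empty_junction_tbl())
  }
  has_tissue <- "tissue" %in% names(candidates)
  if (!has_tissue) {
    candidates$tissue <- "all"
  }
  per_tissue <- candidates %>%
    distinct(across(all_of(c(key, "tissue", "read_id")))) %>%
    count(across(all_of(c(key, "tissue"))), name = "support")
  if (pooled) {
    totals <- per_tissue %>%
      group_by(across(all_of(key))) %>%
      summarise(total = sum(.data$support), .groups = "drop") %>%
      filter(.data$total >= min_support)
    per_tissue <- per_tissue %>%
      inner_join(totals[key], by = key)
  } else {
    per_tissue <- per_tissue %>% filter(.data$support >= min_support)
  }
  out <- per_tissue %>%
    group_by(across(all_of(key))) %>%
    summarise(support = sum(.data$support), .groups = "drop") %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(
      splice_signal = "GT/AG",
      name = sprintf("bsj_%05d", row_number())
    ) %>%
    select("chrom", "start", "end", "strand", "splice_signal",
           "support", "name")
  if (has_tissue) {
    attr(out, "tissue_support") <- per_tissue %>%
      arrange(.data$chrom, .data$start, .data$end, .data$tissue)
  }
  out
}

empty_junction_tbl <- function() {
  tibble(chrom = character(0), start = integer(0), end = integer(0),
         strand = character(0), splice_signal = character(0),
         support = integer(0), name = character(0))
}

#' Detect back-splice junctions in unmapped reads
#'
#' The full caller: terminal anchors of each unmapped read (tried in both
#' orientations against the forward genome) are aligned exactly and must be
#' unique in the genome; anchor pairs in reversed genomic order within the
#' span limits are extended across the read interior under the mismatch
#' budget; the breakpoint with canonical GT/AG flanks is selected; and
#' junctions are aggregated with the `min_support` filter. Reads whose
#' orientations yield more than one distinct junction are discarded as
#' ambiguous.
#'
#' @param reads unmapped read tibble (`read_id`, `seq`, `qual`, optionally
#'   `tissue`).
#' @param index a [build_index()] result whose `k` equals `anchor_len`.
#' @param anchor_len anchor length (default 20).
#' @param max_mismatch extension mismatch budget (default 2).
#' @param min_support minimum supporting reads per junction (default 2).
#' @param min_span,max_span admissible junction extent in bases (defaults
#'   50 and 100000).
#' @param pooled see [aggregate_junctions()].
#' @return an object of class `circ_detection`: list with `junctions` (see
#'   [aggregate_junctions()]), `candidates` (per-read calls), `stats`
#'   (one-row attrition tibble, including the anchor-mappable fraction) and
#'   `params`.
#' @export
detect_backsplice <- function(reads, index, anchor_len = 20L,
                              max_mismatch = 2L, min_support = 2L,
                              min_span = 50L, max_span = 100000L,
                              pooled = FALSE) {
  assert_reads_tbl(reads)
  if (index$k != anchor_len) {
    abort(sprintf(
      "index seed length (%d) must equal `anchor_len` (%d) for exact anchor lookup",
      index$k, anchor_len
    ))
  }
  A <- anchor_len
  lens <- nchar(reads$seq)
  valid <- lens >= 2L * A
  rd <- reads[valid, , drop = FALSE]
  n_short <- sum(!valid)

  cand_rows <- list()
  # stages: 0 anchors unmappable, 1 not reversed/span, 2 mismatch overflow,
  # 3 no signal, 4 called
  stage <- integer(nrow(rd))

  if (nrow(rd)) {
    orient <- list("fwd" = rd$seq, "rev" = revcomp(rd$seq))
    L <- nchar(rd$seq)
    all_anchors <- unique(unlist(lapply(orient, function(s)
      c(substr(s, 1L, A), substr(s, nchar(s) - A + 1L, nchar(s))))))
    info <- index$dt[
      data.table::data.table(kmer = all_anchors), on = "kmer",
      nomatch = NULL
    ][, list(n = .N, chrom = chrom[1], pos = pos[1], strand = strand[1]),
      by = "kmer"]
    lookup <- function(km) {
      i <- match(km, info$kmer)
      if (is.na(i)) return(NULL)
      info[i, ]
    }

    for (r in seq_len(nrow(rd))) {
      found <- list()
      for (o in names(orient)) {
        s <- orient[[o]][r]
        hk <- lookup(substr(s, 1L, A))
        tk <- lookup(substr(s, L[r] - A + 1L, L[r]))
        if (is.null(hk) || is.null(tk) || hk$n != 1L || tk$n != 1L ||
            hk$strand != "+" || tk$strand != "+") {
          next
        }
        stage[r] <- max(stage[r], 1L)
        if (hk$chrom != tk$chrom) next
        h <- hk$pos
        t <- tk$pos
        span <- h - t + L[r] - A
        if (h <= t || span < min_span || span > max_span) next
        stage[r] <- max(stage[r], 2L)
        call <- call_breakpoint(s, index$seqs[[hk$chrom]], h, t,
                                anchor_len = A,
                                max_mismatch = max_mismatch)
        if (!nrow(call)) {
          if (identical(attr(call, "reason"), "no_signal")) {
            stage[r] <- max(stage[r], 3L)
          }
          next
        }
        stage[r] <- 4L
        call$chrom <- hk$chrom
        call$orientation <- o
        found[[length(found) + 1L]] <- call
      }
      if (length(found)) {
        f <- bind_rows(found) %>%
          distinct(.data$chrom, .data$start, .data$end, .data$strand,
                   .keep_all = TRUE)
        if (nrow(f) > 1L) {
          stage[r] <- 5L  # ambiguous: conflicting junctions across splits
          next
        }
        f$read_id <- rd$read_id[r]
        f$tissue <- if ("tissue" %in% names(rd)) rd$tissue[r]
                    else NA_character_
        cand_rows[[length(cand_rows) + 1L]] <- f
      }
    }
  }

  candidates <- bind_rows(cand_rows)
  if (!nrow(candidates)) {
    candidates <- tibble(
      chrom = character(0), start = integer(0), end = integer(0),
      strand = character(0), split = integer(0), mismatches = integer(0),
      orientation = character(0), read_id = character(0),
      tissue = character(0)
    )
  }
  if (all(is.na(candidates$tissue))) candidates$tissue <- NULL

  junctions <- aggregate_junctions(candidates, min_support = min_support,
                                   pooled = pooled)
  stats <- tibble(
    n_reads = nrow(reads),
    n_short = n_short,
    n_anchor_mappable = sum(stage >= 1L),
    anchor_mappable_frac = if (nrow(rd)) sum(stage >= 1L) / nrow(rd) else 0,
    n_paired = sum(stage >= 2L),
    n_mismatch_overflow = sum(stage == 2L),
    n_no_signal = sum(stage == 3L),
    n_ambiguous = sum(stage == 5L),
    n_candidate_reads = sum(stage == 4L),
    n_junctions = nrow(junctions)
  )
  structure(
    list(junctions = junctions, candidates = candidates, stats = stats,
         params = list(anchor_len = A, max_mismatch = max_mismatch,
                       min_support = min_support, min_span = min_span,
                       max_span = max_span, pooled = pooled)),
    class = "circ_detection"
  )
}

#' Re-splice the genome across a back-splice junction
#'
#' Reconstructs the transcript-orientation sequence a read would have if it
#' crossed the junction with `b` donor-side bases: a suffix of the donor
#' exon joined to a prefix of the acceptor exon. The simulator emits reads
#' with exactly this construction, and the detector's output invariant is
#' that every supporting read matches such a reconstruction within the
#' mismatch budget for some `b`.
#'
#' @param chrom_seq forward chromosome string.
#' @param start,end 0-based half-open junction coordinates.
#' @param strand junction strand.
#' @param b donor-side length in the read.
#' @param read_len total read length.
#' @return the reconstructed read sequence.
#' @export
resplice_read <- function(chrom_seq, start, end, strand, b, read_len) {
  junction_read(chrom_seq, start, end, strand, b, read_len)
}

#' @export
print.circ_detection <- function(x, ...) {
  cat("<circ_detection>\n")
  cat(sprintf("  %d junction(s) from %d read(s); anchor-mappable %.1f%%\n",
              nrow(x$junctions), x$stats$n_reads,
              100 * x$stats$anchor_mappable_frac))
  if (nrow(x$junctions)) print(x$junctions, n = 10)
  invisible(x)
}

#' @rdname detect_backsplice
#' @param x a `circ_detection`.
#' @param ... unused.
#' @export
tidy.circ_detection <- function(x, ...) {
  out <- x$junctions
  ts <- attr(out, "tissue_support")
  if (!is.null(ts)) {
    attr(out, "tissue_support") <- NULL
    out <- left_join(
      out,
      ts %>% tidyr::pivot_wider(names_from = "tissue",
                                values_from = "support",
                                names_prefix = "support_",
                                values_fill = 0L),
      by = c("chrom", "start", "end", "strand")
    )
  }
  out
}

#' @rdname detect_backsplice
#' @export
glance.circ_detection <- function(x, ...) {
  x$stats
}
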