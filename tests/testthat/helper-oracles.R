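# Independent brute-force oracles used to cross-check the aligner, the
# back-splice caller, sharing arithmetic and the exact test. These scan
# exhaustively and share no code path with the implementations they verify.

# every locus (both strands) where `seq` aligns ungapped with <= max_mismatch
oracle_align <- function(seq, genome, max_mismatch = 2L) {
  rows <- list()
  rc <- circfindr::revcomp(seq)
  L <- nchar(seq)
  for (cn in names(genome)) {
    s <- genome[[cn]]
    n <- nchar(s)
    if (n < L) next
    raw_f <- charToRaw(seq)
    raw_r <- charToRaw(rc)
    for (p in 0:(n - L)) {
      sub <- charToRaw(substr(s, p + 1L, p + L))
      mmf <- sum(sub != raw_f)
      mmr <- sum(sub != raw_r)
      if (mmf <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, pos = p, strand = "+", mismatches = mmf
        )
      }
      if (mmr <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cn, pos = p, strand = "-", mismatches = mmr
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), mismatches = integer(0))
  }
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# all signal-consistent junctions a single error-free read supports, found
# by exact string search of both read fragments against the reference at
# every admissible split offset; both read orientations are searched
oracle_read_junctions <- function(seq, genome, anchor_len = 20L,
                                  min_span = 50L, max_span = 100000L) {
  L <- nchar(seq)
  found <- list()
  for (orient in c("fwd", "rev")) {
    s <- if (orient == "fwd") seq else circfindr::revcomp(seq)
    for (b in anchor_len:(L - anchor_len)) {
      donor <- substr(s, 1L, b)
      acceptor <- substr(s, b + 1L, L)
      for (cn in names(genome)) {
        g <- genome[[cn]]
        don_hits <- all_occurrences(donor, g)      # 0-based starts
        acc_hits <- all_occurrences(acceptor, g)
        for (dh in don_hits) {
          end <- dh + b
          for (ah in acc_hits) {
            start <- ah
            span <- end - start
            if (span < min_span || span > max_span) next
            if (start < 2L || end + 2L > nchar(g)) next
            left <- substr(g, start - 1L, start)
            right <- substr(g, end + 1L, end + 2L)
            strand <- if (left == "AG" && right == "GT") "+"
                      else if (left == "AC" && right == "CT") "-"
                      else NA_character_
            if (is.na(strand)) next
            found[[length(found) + 1L]] <- data.frame(
              chrom = cn, start = start, end = end, strand = strand
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, found)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  unique(out)
}

all_occurrences <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  # gregexpr skips overlapping matches; rescan manually
  out <- integer(0)
  from <- 1L
  repeat {
    h <- regexpr(pattern, substr(subject, from, nchar(subject)),
                 fixed = TRUE)[1]
    if (h == -1L) break
    out <- c(out, from + h - 2L)  # 0-based
    from <- from + h
  }
  out
}

# full caller oracle on error-free reads: per-read enumeration, ambiguity
# drop, exact-coordinate aggregation with the support filter
oracle_backsplice <- function(reads, genome, anchor_len = 20L,
                              min_support = 2L, min_span = 50L,
                              max_span = 100000L) {
  calls <- list()
  for (i in seq_len(nrow(reads))) {
    j <- oracle_read_junctions(reads$seq[i], genome,
                               anchor_len = anchor_len,
                               min_span = min_span, max_span = max_span)
    if (nrow(j) == 1L) {
      calls[[length(calls) + 1L]] <- j
    }
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      support = integer(0)))
  }
  agg <- aggregate(list(support = rep(1L, nrow(out))),
                   by = out[c("chrom", "start", "end", "strand")], FUN = sum)
  agg <- agg[agg$support >= min_support, , drop = FALSE]
  agg[order(agg$chrom, agg$start, agg$end), , drop = FALSE]
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (probabilities from choose() products)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# deterministic per-test RNG scope
with_test_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# small standard fixtures -----------------------------------------------

tiny_sim <- function(seed = 7L, tissues = "brain", n_genes = 3L,
                     chrom_length = 20000L, n_circ = 2L, ...) {
  cfg <- sim_config(chrom_length = chrom_length, n_genes = n_genes,
                    tissues = tissues, n_circ_per_tissue = n_circ,
                    seed = seed, ...)
  sim <- simulate_genome(cfg)
  list(cfg = cfg, sim = sim, lib = simulate_reads(sim))
}

make_reads <- function(seqs, qual_char = "I", ids = NULL,
                       tissue = "t1") {
  tibble::tibble(
    read_id = ids %||% sprintf("r%03d", seq_along(seqs)),
    tissue = tissue,
    seq = seqs,
    qual = strrep(qual_char, nchar(seqs))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic substitution to a different base
flip_base <- function(x) {
  chartr("ACGT", "CGTA", x)
}
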