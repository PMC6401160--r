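#' Simulate per-tissue read libraries with ground truth
#'
#' Emits, for every tissue in the configuration, a library of
#' \itemize{
#'   \item linear-transcript reads tiled along each mature (spliced) mRNA;
#'   \item back-splice-spanning reads for each implanted circRNA: the read is
#'     a suffix of the donor exon followed by a prefix of the acceptor exon,
#'     with the junction placed at least one anchor length from either read
#'     end, at a planted support depth;
#'   \item optionally, uniform substitution errors and low-quality 3' tails.
#' }
#' Implanted junctions are sampled per tissue from a shared candidate pool so
#' that tissues share circRNAs, as real tissue panels do. In `polyA_mode`
#' only linear reads from polyadenylated (protein-coding) transcripts are
#' emitted and the truth set contains zero junctions — the negative control
#' behind polyA false-positive assessment.
#'
#' @param sim a `sim_genome` from [simulate_genome()].
#' @param config a [sim_config()]; defaults to the one stored in `sim`.
#' @return an object of class `sim_reads`: a list with
#'   \describe{
#'     \item{reads}{tibble `read_id`, `tissue`, `seq`, `qual` (Phred+33).}
#'     \item{truth}{list of two tibbles — `junctions` (`junction_id`,
#'       `chrom`, `start`, `end`, `strand`, `tissue`, `support`) and
#'       `provenance` (`read_id`, `tissue`, `origin`, `source_id`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(chrom_length = 20000, n_genes = 3,
#'                                   tissues = "brain",
#'                                   n_circ_per_tissue = 2, seed = 7))
#' lib <- simulate_reads(sim)
#' dplyr::count(lib$truth$provenance, origin)
simulate_reads <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_genome"), inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, simulate_reads_impl(sim, config))
}

simulate_reads_impl <- function(sim, config) {
  chroms <- genome_strings(sim$genome)
  genes <- sim$genes
  L <- config$read_length
  A <- config$anchor_len

  tx <- mature_transcripts(genes, chroms)
  use_genes <- if (config$polyA_mode) {
    genes[genes$biotype == "protein_coding", ]
  } else {
    genes
  }

  pool <- tibble()
  if (!config$polyA_mode) {
    elig <- eligible_junctions(genes)
    pool_size <- min(
      config$n_junction_pool %||% (2L * config$n_circ_per_tissue),
      nrow(elig)
    )
    if (pool_size < config$n_circ_per_tissue) {
      abort(sprintf(
        "junction pool too small: %d eligible exon pairs but %d circRNAs requested per tissue",
        pool_size, config$n_circ_per_tissue
      ))
    }
    pool <- elig[sort(sample.int(nrow(elig), pool_size)), ]
  }

  all_reads <- list()
  all_prov <- list()
  all_truth <- list()

  for (tissue in config$tissues) {
    # linear backbone: tile every mature transcript
    lin <- pmap(use_genes, function(gene_id, ...) {
      t_seq <- tx[[gene_id]]
      if (nchar(t_seq) < L) return(NULL)
      starts <- seq(0L, nchar(t_seq) - L, by = config$tile_step)
      tibble(
        read_id = sprintf("%s:lin:%s:%03d", tissue, gene_id,
                          seq_along(starts)),
        seq = substr0(rep(t_seq, length(starts)), starts, starts + L),
        origin = "linear", source_id = gene_id
      )
    })
    lin <- bind_rows(lin)

    circ <- tibble()
    truth_t <- tibble()
    if (!config$polyA_mode && config$n_circ_per_tissue > 0L) {
      sel <- pool[sort(sample.int(nrow(pool), config$n_circ_per_tissue)), ]
      supports <- resample(
        seq(config$junction_support[1], config$junction_support[2]),
        nrow(sel), replace = TRUE
      )
      circ <- pmap(
        cbind(sel, support = supports),
        function(junction_id, chrom, start, end, strand,
                 left_exon_len, right_exon_len, support, ...) {
          b <- sample_junction_offsets(support, L, A, strand,
                                       left_exon_len, right_exon_len)
          tibble(
            read_id = sprintf("%s:bsj:%s:%02d", tissue, junction_id,
                              seq_len(support)),
            seq = vapply(b, function(bi)
              junction_read(chroms[[chrom]], start, end, strand, bi, L),
              character(1)),
            origin = "backsplice", source_id = junction_id
          )
        }
      )
      circ <- bind_rows(circ)
      truth_t <- tibble(
        junction_id = sel$junction_id, chrom = sel$chrom,
        start = sel$start, end = sel$end, strand = sel$strand,
        tissue = tissue, support = supports
      )
    }

    noise <- tibble()
    if (config$n_noise_reads > 0L) {
      ch <- sample(names(chroms), config$n_noise_reads, replace = TRUE)
      ps <- vapply(ch, function(c.)
        sample.int(nchar(chroms[[c.]]) - L + 1L, 1L) - 1L, integer(1))
      noise <- tibble(
        read_id = sprintf("%s:noise:%03d", tissue,
                          seq_len(config$n_noise_reads)),
        seq = mapply(function(c., p) substr0(chroms[[c.]], p, p + L),
                     ch, ps, USE.NAMES = FALSE),
        origin = "noise", source_id = NA_character_
      )
    }

    lib <- bind_rows(lin, circ, noise)
    lib$seq <- apply_substitution_errors(lib$seq, config$error_rate)
    lib$qual <- make_qualities(nchar(lib$seq),
                               config$low_qual_tail_fraction)
    lib$tissue <- tissue

    if (config$paired) {
      mates <- emit_mates(lib, tx, chroms, truth_t, config)
      lib <- bind_rows(lib, mates)
    }

    all_reads[[tissue]] <- lib[, c("read_id", "tissue", "seq", "qual")]
    all_prov[[tissue]] <- tibble(
      read_id = lib$read_id, tissue = tissue,
      origin = lib$origin, source_id = lib$source_id
    )
    all_truth[[tissue]] <- truth_t
  }

  structure(
    list(
      reads = bind_rows(all_reads),
      truth = list(
        junctions = bind_rows(all_truth),
        provenance = bind_rows(all_prov)
      ),
      config = config
    ),
    class = "sim_reads"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mature (spliced) transcript sequence per gene, transcript orientation
mature_transcripts <- function(genes, chroms) {
  out <- pmap(genes, function(gene_id, chrom, strand, exon_starts,
                              exon_ends, ...) {
    s <- paste(mapply(function(a, b) substr0(chroms[[chrom]], a, b),
                      exon_starts, exon_ends),
               collapse = "")
    if (strand == "-") revcomp(s) else s
  })
  setNames(out, genes$gene_id)
}

# admissible donor-side lengths b: junction >= anchor_len from both read
# ends, and both read fragments contained in their boundary exons
sample_junction_offsets <- function(n, read_len, anchor_len, strand,
                                    left_exon_len, right_exon_len) {
  if (strand == "+") {
    lo <- max(anchor_len, read_len - left_exon_len)
    hi <- min(read_len - anchor_len, right_exon_len)
  } else {
    lo <- max(anchor_len, read_len - right_exon_len)
    hi <- min(read_len - anchor_len, left_exon_len)
  }
  if (lo > hi) {
    abort("junction-spanning read does not fit inside the joined exons")
  }
  resample(seq(lo, hi), n, replace = n > (hi - lo + 1L))
}

# transcript-orientation read crossing the back-splice junction:
# b bases of donor-exon suffix followed by (read_len - b) bases of
# acceptor-exon prefix
junction_read <- function(chrom_seq, start, end, strand, b, read_len) {
  if (strand == "+") {
    paste0(substr0(chrom_seq, end - b, end),
           substr0(chrom_seq, start, start + (read_len - b)))
  } else {
    paste0(revcomp(substr0(chrom_seq, start, start + b)),
           revcomp(substr0(chrom_seq, end - (read_len - b), end)))
  }
}

apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# high-quality bases (Phred 35-40); a chosen fraction of reads gets a
# low-quality 3' tail (Phred 2-20) to give the trimmer work
make_qualities <- function(lens, low_tail_fraction) {
  n <- length(lens)
  if (!n) return(character(0))
  tails <- runif(n) < low_tail_fraction
  vapply(seq_len(n), function(i) {
    q <- sample(35:40, lens[i], replace = TRUE)
    if (tails[i]) {
      tl <- min(sample(10:60, 1L), lens[i] - 1L)
      q[(lens[i] - tl + 1L):lens[i]] <- sample(2:20, tl, replace = TRUE)
    }
    intToUtf8(q + 33L)
  }, character(1))
}

# mates come from the linear backbone: a nearby genomic/transcript window in
# opposite orientation, so mates map contiguously and add no junction logic
emit_mates <- function(lib, tx, chroms, truth_t, config) {
  L <- config$read_length
  frag <- min(2L * L + 50L, 3L * L)
  rows <- pmap(lib, function(read_id, seq, origin, source_id, ...) {
    if (origin == "linear") {
      t_seq <- tx[[source_id]]
      p <- regexpr(substr(seq, 1L, 30L), t_seq, fixed = TRUE)[1] - 1L
      if (p < 0L) p <- 0L
      m_start <- max(0L, min(p + frag - L, nchar(t_seq) - L))
      mseq <- revcomp(substr0(t_seq, m_start, m_start + L))
    } else if (origin == "backsplice") {
      j <- truth_t[truth_t$junction_id == source_id, ][1, ]
      w <- if (j$strand == "+") {
        substr0(chroms[[j$chrom]], j$start, j$start + L)
      } else {
        substr0(chroms[[j$chrom]], j$end - L, j$end)
      }
      mseq <- revcomp(w)
    } else {
      return(NULL)
    }
    tibble(read_id = paste0(read_id, "/2"), seq = mseq,
           origin = origin, source_id = source_id)
  })
  mates <- bind_rows(rows)
  if (!nrow(mates)) return(mates)
  mates$seq <- apply_substitution_errors(mates$seq, config$error_rate)
  mates$qual <- make_qualities(nchar(mates$seq),
                               config$low_qual_tail_fraction)
  mates$tissue <- lib$tissue[1]
  mates
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads>\n")
  tab <- x$truth$provenance %>% count(.data$tissue, .data$origin)
  cat(sprintf("  %d reads across %d tissue(s); %d truth junction rows\n",
              nrow(x$reads), length(unique(x$reads$tissue)),
              nrow(x$truth$junctions)))
  print(tidyr::pivot_wider(tab, names_from = "origin", values_from = "n",
                           values_fill = 0L), n = Inf)
  invisible(x)
}
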