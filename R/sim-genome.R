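#' Simulate a toy genome with spliced gene models
#'
#' Generates `n_chromosomes` random chromosomes (uniform A/C/G/T background)
#' and places non-overlapping multi-exon gene models on them. Every intron is
#' given canonical splice signals on the annotated strand — genomic `GT`
#' immediately 3' of each donor exon end and `AG` immediately 5' of each
#' acceptor exon start (`CT`/`AC` on the forward strand for minus-strand
#' genes) — so that back-splice junctions built from internal exon boundaries
#' always carry signal-consistent flanks. Genes are assigned a
#' `protein_coding` or `lncRNA` biotype; protein-coding genes get a CDS span
#' strictly inside their first and last exons, from which 5'/3' UTRs are
#' derivable.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_genome`: a list with
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] of chromosome sequences.}
#'     \item{genes}{tibble of gene models: `gene_id`, `chrom`, `strand`,
#'       `biotype`, `gene_start`, `gene_end`, `n_exons`, `exon_starts`,
#'       `exon_ends` (0-based half-open, list-columns), `cds_start`,
#'       `cds_end` (`NA` for lncRNA).}
#'     \item{config}{the input configuration.}
#'   }
#' @seealso [simulate_reads()] for the matching read libraries.
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(chrom_length = 20000, n_genes = 3,
#'                                   seed = 7))
#' sim$genes
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chroms <- vapply(chrom_names, function(.)
    paste(sample(DNA_BASES, config$chrom_length, replace = TRUE),
          collapse = ""),
    character(1))

  # per-gene structure, then sequential placement per chromosome
  n_ex <- resample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                   config$n_genes, replace = TRUE)
  ex_lens <- lapply(n_ex, function(k)
    resample(seq(config$exon_length[1], config$exon_length[2]), k,
             replace = TRUE))
  in_lens <- lapply(n_ex, function(k)
    resample(seq(config$intron_length[1], config$intron_length[2]),
             max(k - 1L, 0L), replace = TRUE))
  spans <- mapply(function(e, i) sum(e) + sum(i), ex_lens, in_lens)
  gene_chrom <- rep_len(seq_len(config$n_chromosomes), config$n_genes)

  margin <- 1100L   # keeps 1-kb flanks on-chromosome
  min_gap <- 2300L  # keeps neighbouring flanks disjoint
  starts <- integer(config$n_genes)
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(gene_chrom == ci)
    if (!length(idx)) next
    starts[idx] <- place_genes(spans[idx], config$chrom_length,
                               margin, min_gap)
  }

  biotype <- sample(c("protein_coding", "lncRNA"), config$n_genes,
                    replace = TRUE,
                    prob = c(1 - config$lnc_fraction, config$lnc_fraction))
  biotype[1] <- "protein_coding"
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    el <- ex_lens[[g]]
    il <- in_lens[[g]]
    es <- integer(length(el))
    ee <- integer(length(el))
    pos <- starts[g]
    for (i in seq_along(el)) {
      es[i] <- pos
      ee[i] <- pos + el[i]
      pos <- ee[i] + if (i < length(el)) il[i] else 0L
    }
    cds <- c(NA_integer_, NA_integer_)
    if (biotype[g] == "protein_coding") {
      cds <- c(es[1] + resample(20:60, 1),
               ee[length(ee)] - resample(20:60, 1))
    }
    chrom_i <- gene_chrom[g]
    chroms[chrom_i] <- force_splice_signals(chroms[chrom_i], es, ee,
                                            strand[g])
    genes[[g]] <- tibble(
      gene_id = sprintf("gene%03d", g),
      chrom = chrom_names[chrom_i],
      strand = strand[g],
      biotype = biotype[g],
      gene_start = es[1], gene_end = ee[length(ee)],
      n_exons = length(el),
      exon_starts = list(es), exon_ends = list(ee),
      cds_start = cds[1], cds_end = cds[2]
    )
  }

  structure(
    list(
      genome = Biostrings::DNAStringSet(setNames(chroms, chrom_names)),
      genes = bind_rows(genes),
      config = config
    ),
    class = "sim_genome"
  )
}

# lay out gene spans left-to-right with randomised slack between them
place_genes <- function(spans, chrom_length, margin, min_gap) {
  k <- length(spans)
  need <- sum(spans) + (k - 1L) * min_gap
  avail <- chrom_length - 2L * margin
  if (need > avail) {
    abort(sprintf(
      "chromosome too small: %d genes need %d bp (incl. gaps/flanks) but only %d bp are available",
      k, need, avail
    ))
  }
  per <- (avail - need) %/% (k + 1L)
  starts <- integer(k)
  pos <- margin
  for (i in seq_len(k)) {
    pos <- pos + if (per > 0L) sample(0:per, 1L) else 0L
    starts[i] <- pos
    pos <- pos + spans[i] + if (i < k) min_gap else 0L
  }
  starts
}

# write canonical splice dinucleotides at every intron boundary;
# forward-genome letters depend on the gene strand
force_splice_signals <- function(chrom, exon_starts, exon_ends, strand) {
  n <- length(exon_starts)
  if (n < 2L) return(chrom)
  for (i in seq_len(n - 1L)) {
    is <- exon_ends[i]        # intron [is, ie), 0-based
    ie <- exon_starts[i + 1L]
    if (strand == "+") {
      substr(chrom, is + 1L, is + 2L) <- "GT"
      substr(chrom, ie - 1L, ie) <- "AG"
    } else {
      substr(chrom, is + 1L, is + 2L) <- "CT"
      substr(chrom, ie - 1L, ie) <- "AC"
    }
  }
  chrom
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>\n")
  cat(sprintf("  %d chromosome(s): %s\n", length(x$genome),
              paste(sprintf("%s (%d bp)", names(x$genome),
                            Biostrings::width(x$genome)), collapse = ", ")))
  cat(sprintf("  %d gene model(s): %d protein_coding, %d lncRNA\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              sum(x$genes$biotype == "lncRNA")))
  invisible(x)
}

#' Enumerate back-splice-eligible exon pairs
#'
#' Lists every (acceptor exon, donor exon) pair usable as a back-splice
#' junction: both exons internal (flanked by an intron on the junction side)
#' so the genome carries the GT/AG signal at the breakpoints by construction.
#' Junction coordinates follow the BED convention: `start` is the first base
#' of the forward-leftmost exon, `end` one past the last base of the
#' forward-rightmost exon of the pair.
#'
#' @param genes gene-model tibble from [simulate_genome()].
#' @return tibble with `junction_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and the lengths of the two boundary exons (`left_exon_len`,
#'   `right_exon_len`).
#' @export
eligible_junctions <- function(genes) {
  out <- pmap(genes, function(gene_id, chrom, strand, exon_starts, exon_ends,
                              n_exons, ...) {
    if (n_exons < 3L) return(NULL)
    pairs <- expand.grid(i = 2:(n_exons - 1L), j = 2:(n_exons - 1L))
    pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
    tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = exon_starts[pairs$i], end = exon_ends[pairs$j],
      left_exon_len = exon_ends[pairs$i] - exon_starts[pairs$i],
      right_exon_len = exon_ends[pairs$j] - exon_starts[pairs$j]
    )
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    return(tibble(junction_id = character(0), gene_id = character(0),
                  chrom = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  left_exon_len = integer(0), right_exon_len = integer(0)))
  }
  out <- arrange(out, .data$chrom, .data$start, .data$end)
  out$junction_id <- sprintf("bsj%04d", seq_len(nrow(out)))
  out[, c("junction_id", "gene_id", "chrom", "start", "end", "strand",
          "left_exon_len", "right_exon_len")]
}
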