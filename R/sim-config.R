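#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator: a toy
#' multi-chromosome genome carrying multi-exon protein-coding and lncRNA gene
#' models with canonical GT/AG splice signals, and per-tissue read libraries
#' made of linear-transcript reads plus back-splice-spanning reads at a
#' controlled support depth. In `polyA_mode` the library emulates a
#' polyA-selected preparation: only linear polyadenylated (protein-coding)
#' transcripts are sequenced and no back-splice read is emitted, which is the
#' negative control used to operationalise false-positive assessment.
#'
#' @param n_chromosomes number of chromosomes in the toy genome.
#' @param chrom_length length of each chromosome in bases.
#' @param n_genes number of gene models to place (spread across chromosomes).
#' @param exons_per_gene integer range `c(min, max)` of exons per gene; back-
#'   splice junctions need internal exons, so the minimum is 3.
#' @param n_circ_per_tissue circRNAs implanted per tissue, sampled from a
#'   shared junction pool so that tissues share junctions naturally.
#' @param tissues character vector of tissue labels.
#' @param read_length read length in bases (default 101, typical of HiSeq
#'   libraries); must be at least twice the anchor length.
#' @param junction_support integer range `c(min, max)` of reads planted per
#'   implanted junction.
#' @param error_rate per-base substitution error probability in `[0, 1]`.
#' @param seed integer seed; identical config + seed reproduces byte-identical
#'   FASTA/FASTQ/BED outputs.
#' @param polyA_mode logical; emulate a polyA-selected library (no genuine
#'   back-splice reads, protein-coding transcripts only).
#' @param anchor_len anchor length the downstream caller will use; reads keep
#'   the junction at least this far from both read ends.
#' @param exon_length integer range of exon lengths; the minimum must be at
#'   least `read_length` so a junction-spanning read stays within the two
#'   joined exons.
#' @param intron_length integer range of intron lengths.
#' @param lnc_fraction fraction of genes assigned the lncRNA biotype (the
#'   first gene is always protein-coding so polyA libraries are non-empty).
#' @param tile_step tiling step, in bases, of linear reads along each mature
#'   transcript.
#' @param n_junction_pool size of the shared junction candidate pool; `NULL`
#'   uses `2 * n_circ_per_tissue` (capped at the number of eligible exon
#'   pairs).
#' @param low_qual_tail_fraction fraction of reads given a low-quality 3'
#'   tail (Phred 2-20), to exercise quality trimming; default 0.
#' @param paired logical; also emit a mate read drawn from the linear
#'   backbone near each fragment. Back-splice evidence is per-read, so mates
#'   add coverage, not logic.
#' @param n_noise_reads random intergenic-noise reads per tissue (default 0).
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000, n_genes = 4,
#'                   tissues = c("brain", "heart"), seed = 7)
#' cfg$read_length
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 50000L,
                       n_genes = 10L,
                       exons_per_gene = c(3L, 4L),
                       n_circ_per_tissue = 8L,
                       tissues = c("blood", "brain", "muscle", "heart", "gills"),
                       read_length = 101L,
                       junction_support = c(2L, 5L),
                       error_rate = 0,
                       seed = 1L,
                       polyA_mode = FALSE,
                       anchor_len = 20L,
                       exon_length = c(150L, 250L),
                       intron_length = c(250L, 450L),
                       lnc_fraction = 0.3,
                       tile_step = 50L,
                       n_junction_pool = NULL,
                       low_qual_tail_fraction = 0,
                       paired = FALSE,
                       n_noise_reads = 0L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    n_circ_per_tissue = as.integer(n_circ_per_tissue),
    tissues = as.character(tissues),
    read_length = as.integer(read_length),
    junction_support = as.integer(junction_support),
    error_rate = as.numeric(error_rate),
    seed = as.integer(seed),
    polyA_mode = isTRUE(polyA_mode),
    anchor_len = as.integer(anchor_len),
    exon_length = as.integer(exon_length),
    intron_length = as.integer(intron_length),
    lnc_fraction = as.numeric(lnc_fraction),
    tile_step = as.integer(tile_step),
    n_junction_pool = if (is.null(n_junction_pool)) NULL
                      else as.integer(n_junction_pool),
    low_qual_tail_fraction = as.numeric(low_qual_tail_fraction),
    paired = isTRUE(paired),
    n_noise_reads = as.integer(n_noise_reads)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$exons_per_gene) == 2L, length(cfg$junction_support) == 2L,
    length(cfg$exon_length) == 2L, length(cfg$intron_length) == 2L
  )
  pos <- c(
    n_chromosomes = cfg$n_chromosomes, chrom_length = cfg$chrom_length,
    n_genes = cfg$n_genes, read_length = cfg$read_length,
    anchor_len = cfg$anchor_len, tile_step = cfg$tile_step
  )
  if (any(pos <= 0L)) {
    abort(sprintf("all counts must be positive; offending: %s",
                  paste(names(pos)[pos <= 0L], collapse = ", ")))
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 1) {
    abort("`error_rate` must lie in [0, 1]")
  }
  if (cfg$read_length < 2L * cfg$anchor_len) {
    abort(sprintf(
      "`read_length` (%d) must be at least twice the anchor length (%d) so head and tail anchors are extractable",
      cfg$read_length, 2L * cfg$anchor_len
    ))
  }
  if (cfg$exons_per_gene[1] < 3L) {
    abort("`exons_per_gene` minimum is 3: back-splice junctions use internal exon boundaries")
  }
  if (cfg$exon_length[1] < cfg$read_length) {
    abort("minimum `exon_length` must be >= `read_length` so junction reads stay within the joined exons")
  }
  if (length(cfg$tissues) < 1L || anyDuplicated(cfg$tissues)) {
    abort("`tissues` must be a non-empty vector of distinct labels")
  }
  if (!cfg$polyA_mode && cfg$n_circ_per_tissue < 1L) {
    abort("`n_circ_per_tissue` must be positive unless `polyA_mode = TRUE`")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome : %d chromosome(s) x %d bp, %d genes\n",
              x$n_chromosomes, x$chrom_length, x$n_genes))
  cat(sprintf("  reads  : %d nt, error rate %g, tissues: %s\n",
              x$read_length, x$error_rate, paste(x$tissues, collapse = ", ")))
  cat(sprintf("  circles: %d per tissue, support %d-%d%s\n",
              x$n_circ_per_tissue, x$junction_support[1], x$junction_support[2],
              if (x$polyA_mode) " [polyA mode: suppressed]" else ""))
  invisible(x)
}
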