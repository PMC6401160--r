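#' Run the full circRNA discovery pipeline on a read set
#'
#' Convenience composition of the discovery stages: 3' quality trimming,
#' contiguous end-to-end alignment to discard linearly explained reads,
#' and back-splice detection on the unmapped remainder. When the reads
#' carry a `tissue` column, detection support is counted per tissue.
#'
#' @param reads read tibble (`read_id`, `seq`, `qual`, optionally `tissue`).
#' @param genome `DNAStringSet`, named character vector or `sim_genome`.
#' @param phred_cutoff,min_len trimming parameters (see [quality_trim()]).
#' @param anchor_len,max_mismatch,min_support,min_span,max_span,pooled
#'   detection parameters (see [detect_backsplice()]).
#' @return an object of class `circ_pipeline`: list with `junctions`,
#'   `detection` (the [detect_backsplice()] result), `partition_summary`,
#'   `trim_summary` and `index`.
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(chrom_length = 20000, n_genes = 3,
#'                                   tissues = "brain",
#'                                   n_circ_per_tissue = 2, seed = 11))
#' lib <- simulate_reads(sim)
#' res <- run_circ_pipeline(lib$reads, sim)
#' res$junctions
run_circ_pipeline <- function(reads, genome, phred_cutoff = 30L,
                              min_len = 2L * anchor_len, anchor_len = 20L,
                              max_mismatch = 2L, min_support = 2L,
                              min_span = 50L, max_span = 100000L,
                              pooled = FALSE) {
  trimmed <- quality_trim(reads, phred_cutoff = phred_cutoff,
                          min_len = min_len)
  index <- build_index(genome, k = anchor_len)
  part <- partition_reads(trimmed, index, max_mismatch = max_mismatch)
  det <- detect_backsplice(part$unmapped, index, anchor_len = anchor_len,
                           max_mismatch = max_mismatch,
                           min_support = min_support,
                           min_span = min_span, max_span = max_span,
                           pooled = pooled)
  structure(
    list(
      junctions = det$junctions,
      detection = det,
      partition_summary = part$summary,
      trim_summary = trim_summary(trimmed),
      index = index
    ),
    class = "circ_pipeline"
  )
}

#' @export
print.circ_pipeline <- function(x, ...) {
  cat("<circ_pipeline>\n")
  cat(sprintf("  trim   : %d/%d reads kept\n", x$trim_summary$n_out,
              x$trim_summary$n_in))
  cat(sprintf("  linear : %.1f%% mapped overall\n",
              100 * sum(x$partition_summary$n_mapped) /
                max(1L, sum(x$partition_summary$n_reads))))
  cat(sprintf("  circles: %d junction(s) detected\n", nrow(x$junctions)))
  invisible(x)
}

#' @rdname run_circ_pipeline
#' @param x a `circ_pipeline`.
#' @param ... unused.
#' @export
tidy.circ_pipeline <- function(x, ...) {
  tidy(x$detection)
}

#' @rdname run_circ_pipeline
#' @export
glance.circ_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble(
      n_reads_in = x$trim_summary$n_in,
      n_reads_trimmed_out = x$trim_summary$n_out,
      mapped_frac = sum(x$partition_summary$n_mapped) /
        max(1L, sum(x$partition_summary$n_reads))
    ),
    glance(x$detection)
  )
}
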