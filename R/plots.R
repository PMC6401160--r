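# ggplot2 views of the result objects

#' Plot tissue-sharing structure
#'
#' Bar chart of junction counts by the number of tissues sharing them,
#' annotated with percentages of the union.
#'
#' @param x a [sharing_summary()] result.
#' @return a ggplot object.
#' @export
plot_tissue_sharing <- function(x) {
  stopifnot(inherits(x, "sharing_summary"))
  df <- x$by_k
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$k), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f%%", .data$percent)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = "tissues sharing the junction",
                  y = "circRNA junctions",
                  title = sprintf("Tissue sharing (%d junctions)",
                                  x$total)) +
    ggplot2::theme_minimal()
}

#' Plot length-normalised context densities
#'
#' @param x a [context_report()].
#' @return a ggplot object.
#' @export
plot_context_density <- function(x) {
  stopifnot(inherits(x, "context_report"))
  df <- x$categories %>% filter(!is.na(.data$density_per_mb))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, -.data$density_per_mb),
    y = .data$density_per_mb
  )) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = NULL, y = "junctions per Mb of feature",
                  title = "Genomic-context density (length-normalised)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot per-chromosome junction density
#'
#' @param x a [context_report()].
#' @return a ggplot object.
#' @export
plot_chrom_density <- function(x) {
  stopifnot(inherits(x, "context_report"))
  ggplot2::ggplot(x$chromosomes, ggplot2::aes(
    x = .data$chrom, y = .data$density_per_mb
  )) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "junctions per Mb",
                  title = "Per-chromosome junction density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_context_density
#' @param object a `context_report`.
#' @param ... unused.
#' @export
autoplot.context_report <- function(object, ...) {
  plot_context_density(object)
}

#' @rdname plot_tissue_sharing
#' @param object a `sharing_summary`.
#' @param ... unused.
#' @export
autoplot.sharing_summary <- function(object, ...) {
  plot_tissue_sharing(object)
}
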