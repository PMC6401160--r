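# Multi-tissue integration: junction identity across libraries is exact
# (chrom, start, end, strand) — junction sets are intersected on
# coordinates, as cross-pipeline and cross-library comparisons of
# back-splice catalogues are — with an optional +/- slop window for callers
# that differ by convention.

JUNCTION_KEY <- c("chrom", "start", "end", "strand")

#' Build a junction-by-tissue sharing matrix
#'
#' @param junctions either a single tibble with a `tissue` and `support`
#'   column, or a named list of per-tissue junction tibbles (`chrom`,
#'   `start`, `end`, `strand`, `support`).
#' @return a `tissue_matrix`: a tibble with the junction key columns plus
#'   one support column per tissue (0 = not detected); every row has at
#'   least one nonzero cell.
#' @export
build_sharing_matrix <- function(junctions) {
  if (is.data.frame(junctions)) {
    if (!"tissue" %in% names(junctions)) {
      abort("a single junction tibble needs a `tissue` column; otherwise pass a named list")
    }
    long <- junctions
  } else {
    if (is.null(names(junctions)) || any(!nzchar(names(junctions)))) {
      abort("the per-tissue list must be named by tissue label")
    }
    long <- bind_rows(imap(junctions, function(tbl, tis) {
      tbl$tissue <- tis
      tbl
    }))
  }
  if (!nrow(long)) abort("no junctions supplied")
  if (!"support" %in% names(long)) long$support <- 1L
  tissues <- unique(long$tissue)
  out <- long %>%
    group_by(across(all_of(c(JUNCTION_KEY, "tissue")))) %>%
    summarise(support = sum(.data$support), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "support",
                       values_fill = 0L) %>%
    arrange(.data$chrom, .data$start, .data$end)
  for (tis in setdiff(tissues, names(out))) out[[tis]] <- 0L
  structure(out, class = c("tissue_matrix", class(out)),
            tissues = tissues)
}

matrix_tissues <- function(mat) {
  attr(mat, "tissues") %||% setdiff(names(mat), JUNCTION_KEY)
}

#' Tissue-specificity summary of a sharing matrix
#'
#' Counts tissue-restricted junctions (detected in exactly one tissue),
#' junctions shared by k tissues for every k, and junctions present in all
#' tissues; percentages are taken against the union size and rounded
#' half-up to two decimals.
#'
#' @param mat a [build_sharing_matrix()] result.
#' @return an object of class `sharing_summary`: list with
#'   \describe{
#'     \item{total}{union size.}
#'     \item{summary}{tibble `class` (`restricted`, `shared`,
#'       `shared_all`), `n`, `percent`.}
#'     \item{by_k}{tibble `k` (number of tissues), `n`, `percent`.}
#'     \item{restricted_by_tissue}{tibble `tissue`, `n`.}
#'   }
#' @export
sharing_summary <- function(mat) {
  tissues <- matrix_tissues(mat)
  supp <- as.matrix(as.data.frame(mat)[, tissues, drop = FALSE])
  if (!nrow(supp)) abort("empty sharing matrix")
  k <- rowSums(supp > 0L)
  if (any(k == 0L)) abort("sharing matrix has rows with no supporting tissue")
  total <- nrow(supp)
  n_restricted <- sum(k == 1L)
  n_shared <- sum(k >= 2L)
  n_all <- sum(k == length(tissues))
  n_by_k <- vapply(seq_along(tissues), function(i) sum(k == i), numeric(1))
  by_k <- tibble(
    k = seq_along(tissues),
    n = n_by_k,
    percent = overlap_percent(n_by_k, total)
  )
  restricted_by_tissue <- tibble(
    tissue = tissues,
    n = vapply(tissues, function(tis)
      sum(k == 1L & supp[, tis] > 0L), numeric(1))
  )
  structure(
    list(
      total = total,
      summary = tibble(
        class = c("restricted", "shared", "shared_all"),
        n = c(n_restricted, n_shared, n_all),
        percent = overlap_percent(c(n_restricted, n_shared, n_all), total)
      ),
      by_k = by_k,
      restricted_by_tissue = restricted_by_tissue
    ),
    class = "sharing_summary"
  )
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d junction(s) in the union\n", x$total))
  print(x$summary)
  invisible(x)
}

#' @rdname sharing_summary
#' @param x a `sharing_summary`.
#' @param ... unused.
#' @export
tidy.sharing_summary <- function(x, ...) {
  x$by_k
}

#' @rdname sharing_summary
#' @export
glance.sharing_summary <- function(x, ...) {
  tibble(
    total = x$total,
    n_restricted = x$summary$n[1], pct_restricted = x$summary$percent[1],
    n_shared = x$summary$n[2], pct_shared = x$summary$percent[2],
    n_shared_all = x$summary$n[3], pct_shared_all = x$summary$percent[3]
  )
}

# exact or slopped match keys between two junction sets
match_junctions <- function(a, b, slop = 0L) {
  if (slop == 0L) {
    ka <- do.call(paste, a[JUNCTION_KEY])
    kb <- do.call(paste, b[JUNCTION_KEY])
    return(list(a_in_b = ka %in% kb, b_in_a = kb %in% ka))
  }
  pairs <- inner_join(
    a %>% mutate(.ai = row_number()) %>%
      select("chrom", "strand", a_start = "start", a_end = "end", ".ai"),
    b %>% mutate(.bi = row_number()) %>%
      select("chrom", "strand", b_start = "start", b_end = "end", ".bi"),
    by = c("chrom", "strand"), relationship = "many-to-many"
  ) %>%
    filter(abs(.data$a_start - .data$b_start) <= slop,
           abs(.data$a_end - .data$b_end) <= slop)
  list(
    a_in_b = seq_len(nrow(a)) %in% pairs$.ai,
    b_in_a = seq_len(nrow(b)) %in% pairs$.bi
  )
}

#' Compare two junction sets
#'
#' Generic cross-pipeline/cross-library comparison on exact junction
#' coordinates (optionally with a `slop` bp tolerance on both breakpoints).
#' With `slop = 0` the intersection count is symmetric in the argument
#' order; with `slop > 0` per-set matched counts are reported.
#'
#' @param a,b junction tibbles.
#' @param slop breakpoint tolerance in bases (default 0 = exact).
#' @return one-row tibble: `n_a`, `n_b`, `n_common`, `n_a_only`,
#'   `n_b_only`, `n_union` (and `n_b_matched` when `slop > 0`).
#' @export
compare_junction_sets <- function(a, b, slop = 0L) {
  a <- distinct(a, across(all_of(JUNCTION_KEY)))
  b <- distinct(b, across(all_of(JUNCTION_KEY)))
  m <- match_junctions(a, b, slop = slop)
  n_common <- sum(m$a_in_b)
  out <- tibble(
    n_a = nrow(a), n_b = nrow(b),
    n_common = n_common,
    n_a_only = nrow(a) - n_common,
    n_b_only = nrow(b) - sum(m$b_in_a),
    n_union = nrow(a) + nrow(b) - sum(m$b_in_a)
  )
  if (slop > 0L) out$n_b_matched <- sum(m$b_in_a)
  out
}

#' Assess false positives from a polyA-selected library
#'
#' Genuine circRNAs are not polyadenylated, so junctions a pipeline calls
#' in a polyA-selected library estimate its false positives. Reports the
#' polyA-detected count, the overlap with the ribo-depleted catalogue
#' (exact coordinates) and the polyA-only remainder.
#'
#' @param polya junction tibble detected in the polyA library.
#' @param ribo junction tibble detected in ribo-depleted libraries.
#' @return one-row tibble: `n_polya`, `n_common`, `n_polya_only`,
#'   `pct_of_ribo` (common as a percentage of the ribo catalogue).
#' @export
assess_polya_fp <- function(polya, ribo) {
  cmp <- compare_junction_sets(polya, ribo)
  tibble(
    n_polya = cmp$n_a,
    n_common = cmp$n_common,
    n_polya_only = cmp$n_a_only,
    pct_of_ribo = if (cmp$n_b > 0) overlap_percent(cmp$n_common, cmp$n_b)
                  else NA_real_
  )
}

#' Exact enrichment test on a 2x2 table
#'
#' Two-sided Fisher exact (hypergeometric) test for association between two
#' binary gene partitions — canonically, circRNA-forming ability versus
#' having a cross-species orthologue. The odds ratio reported is the sample
#' odds ratio `(a*d)/(b*c)`; a zero cell makes it infinite (or `NaN` for a
#' double-zero diagonal) and is flagged.
#'
#' @param table a 2x2 matrix, or the count `a` with `b`, `c`, `d`.
#' @param b,c,d remaining cell counts when `table` is given as `a`.
#' @return one-row tibble: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `or_degenerate` (zero-cell flag), `p_value`.
#' @export
#' @examples
#' enrichment_test(8, 2, 1, 9)
enrichment_test <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    cells <- as.vector(t(table))
  } else {
    cells <- c(table, b, c, d)
  }
  if (length(cells) != 4L || any(is.na(cells)) || any(cells < 0) ||
      any(cells != floor(cells))) {
    abort("the 2x2 table needs four non-negative integer cells")
  }
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  ft <- stats::fisher.test(m, alternative = "two.sided")
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tibble(
    a = cells[1], b = cells[2], c = cells[3], d = cells[4],
    odds_ratio = or,
    or_degenerate = !is.finite(or),
    p_value = ft$p.value
  )
}
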