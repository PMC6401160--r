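# Genomic-context annotation of junctions: feature derivation from gene
# models, breakpoint-membership mapping, and length-normalised density
# reporting. Overlap is judged on the two junction breakpoints (start and
# end-1), not the whole span — a junction spanning many introns is not
# counted in every one of them — and a junction may carry several labels
# (UTR and intron tallies overlap, as they do in real catalogues).

chrom_lengths_of <- function(x) {
  if (inherits(x, "sim_genome")) x <- x$genome
  if (inherits(x, "genome_index")) return(x$chrom_lengths)
  if (inherits(x, "DNAStringSet")) {
    return(setNames(Biostrings::width(x), names(x)))
  }
  if (is.character(x) && !is.null(names(x))) {
    return(setNames(nchar(x), names(x)))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(setNames(as.integer(x), names(x)))
  }
  abort("cannot derive chromosome lengths: supply a genome or a named integer vector")
}

#' Derive labelled feature intervals from gene models
#'
#' Builds, per category, 0-based half-open interval sets: whole gene spans,
#' exons, CDS portions, introns (inter-exon gaps), 5'/3' UTRs (exonic
#' sequence outside the CDS span, oriented by strand and always re-derived
#' rather than trusted from any annotation file), 1-kb upstream/downstream
#' flanks (strand-oriented, clipped at chromosome ends) and lncRNA loci
#' (gene spans of lncRNA-biotype models, plus any extra loci supplied).
#'
#' @param genes gene-model tibble ([simulate_genome()], [read_genes_gtf()]
#'   or [read_genes_bed12()]).
#' @param chrom_lengths a genome object or named vector of chromosome
#'   lengths (used to clip flanks).
#' @param flank flank size in bases (default 1000).
#' @param lnc optional extra lncRNA loci tibble (`chrom`, `start`, `end`).
#' @return tibble `category`, `chrom`, `start`, `end`, `gene_id`.
#' @export
derive_features <- function(genes, chrom_lengths, flank = 1000L,
                            lnc = NULL) {
  clen <- chrom_lengths_of(chrom_lengths)
  feats <- pmap(genes, function(gene_id, chrom, strand, biotype,
                                gene_start, gene_end, exon_starts,
                                exon_ends, cds_start, cds_end, ...) {
    cl <- clen[[chrom]]
    rows <- list(
      tibble(category = "gene", start = gene_start, end = gene_end),
      tibble(category = "exon", start = exon_starts, end = exon_ends)
    )
    n <- length(exon_starts)
    if (n > 1L) {
      rows <- c(rows, list(
        tibble(category = "intron",
               start = exon_ends[-n], end = exon_starts[-1L])
      ))
    }
    if (!is.na(cds_start)) {
      keep <- exon_ends > cds_start & exon_starts < cds_end
      rows <- c(rows, list(
        tibble(category = "cds",
               start = pmax(exon_starts[keep], cds_start),
               end = pmin(exon_ends[keep], cds_end))
      ))
      left <- intersect_intervals(exon_starts, exon_ends,
                                  gene_start, cds_start)
      right <- intersect_intervals(exon_starts, exon_ends,
                                   cds_end, gene_end)
      if (strand == "+") {
        five <- left; three <- right
      } else {
        five <- right; three <- left
      }
      if (nrow(five)) rows <- c(rows, list(
        tibble(category = "five_utr", start = five$start, end = five$end)))
      if (nrow(three)) rows <- c(rows, list(
        tibble(category = "three_utr", start = three$start,
               end = three$end)))
    }
    up <- if (strand == "+") {
      c(max(0L, gene_start - flank), gene_start)
    } else {
      c(gene_end, min(cl, gene_end + flank))
    }
    dn <- if (strand == "+") {
      c(gene_end, min(cl, gene_end + flank))
    } else {
      c(max(0L, gene_start - flank), gene_start)
    }
    rows <- c(rows, list(
      tibble(category = "upstream1k", start = up[1], end = up[2]),
      tibble(category = "downstream1k", start = dn[1], end = dn[2])
    ))
    if (biotype == "lncRNA") {
      rows <- c(rows, list(
        tibble(category = "lncRNA", start = gene_start, end = gene_end)
      ))
    }
    out <- bind_rows(rows)
    out$chrom <- chrom
    out$gene_id <- gene_id
    out
  })
  feats <- bind_rows(feats)
  if (!is.null(lnc) && nrow(lnc)) {
    feats <- bind_rows(feats, tibble(
      category = "lncRNA", chrom = lnc$chrom, start = lnc$start,
      end = lnc$end, gene_id = NA_character_
    ))
  }
  feats <- feats[feats$end > feats$start, , drop = FALSE]
  feats[, c("category", "chrom", "start", "end", "gene_id")]
}

# 0-based half-open intersection of an interval list with [lo, hi)
intersect_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- e > s
  tibble(start = s[keep], end = e[keep])
}

feature_granges <- function(features) {
  split(
    GenomicRanges::GRanges(
      seqnames = features$chrom,
      ranges = IRanges::IRanges(start = features$start + 1L,
                                end = features$end)
    ),
    features$category
  )
}

#' Map junctions onto genomic-context categories
#'
#' A junction is assigned every category whose intervals contain either of
#' its breakpoints (`start` or `end - 1`); junctions touching no feature
#' are labelled intergenic. With `precedence = TRUE` a single exclusive
#' label is returned instead, using the order CDS > 5'UTR > 3'UTR > exon >
#' intron > flanks > lncRNA > intergenic.
#'
#' @param junctions junction tibble (`chrom`, `start`, `end`, ...).
#' @param features feature tibble from [derive_features()].
#' @param precedence return one exclusive label per junction.
#' @return `junctions` with an added `categories` list-column and
#'   `intergenic` flag (default), or a `category` character column
#'   (`precedence = TRUE`).
#' @export
map_junction_context <- function(junctions, features, precedence = FALSE) {
  cats <- sort(unique(features$category))
  n <- nrow(junctions)
  hit <- matrix(FALSE, nrow = n, ncol = length(cats),
                dimnames = list(NULL, cats))
  if (n) {
    pts <- GenomicRanges::GRanges(
      seqnames = rep(junctions$chrom, 2L),
      ranges = IRanges::IRanges(
        start = c(junctions$start, junctions$end - 1L) + 1L, width = 1L
      )
    )
    grl <- feature_granges(features)
    for (cat in names(grl)) {
      ov <- GenomicRanges::countOverlaps(pts, grl[[cat]]) > 0L
      hit[, cat] <- ov[seq_len(n)] | ov[n + seq_len(n)]
    }
  }
  if (precedence) {
    order_ <- intersect(
      c("cds", "five_utr", "three_utr", "exon", "intron", "upstream1k",
        "downstream1k", "lncRNA", "gene"),
      cats
    )
    junctions$category <- apply(hit, 1L, function(h) {
      first <- order_[h[order_]][1]
      if (is.na(first)) "intergenic" else first
    })
    if (!n) junctions$category <- character(0)
  } else {
    junctions$categories <- lapply(seq_len(n), function(i) {
      cats[hit[i, ]]
    })
    junctions$intergenic <- rowSums(hit) == 0L
  }
  junctions
}

#' Genomic-context report with length-normalised densities
#'
#' Counts junctions per category and per chromosome and normalises each
#' count by the (reduced, non-redundant) feature length, reported per
#' million feature bases; a category with zero bases reports `NA` density.
#' Also reports exclusive-origin counts: junctions whose breakpoints fall
#' in introns but not in exons, and in one UTR class but in neither the CDS
#' nor the other UTR nor an intron.
#'
#' @inheritParams map_junction_context
#' @param chrom_lengths a genome object or named vector of chromosome
#'   lengths.
#' @return an object of class `context_report`: list with `categories`
#'   (`category`, `n_junctions`, `feature_bases`, `density_per_mb`),
#'   `chromosomes` (`chrom`, `n_junctions`, `length`, `density_per_mb`),
#'   `exclusive` (one row: `intron_only`, `five_utr_only`,
#'   `three_utr_only`) and `n_junctions`.
#' @export
context_report <- function(junctions, features, chrom_lengths) {
  clen <- chrom_lengths_of(chrom_lengths)
  mapped <- map_junction_context(junctions, features)
  cats <- sort(unique(features$category))

  bases <- vapply(cats, function(cat) {
    f <- features[features$category == cat, ]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = f$chrom,
      ranges = IRanges::IRanges(start = f$start + 1L, end = f$end)
    ))
    sum(as.numeric(GenomicRanges::width(gr)))
  }, numeric(1))

  counts <- vapply(cats, function(cat)
    sum(map_lgl(mapped$categories, ~ cat %in% .x)), numeric(1))

  counts <- unname(counts)
  bases <- unname(bases)
  categories <- tibble(
    category = c(cats, "intergenic"),
    n_junctions = c(counts, sum(mapped$intergenic)),
    feature_bases = c(bases, NA_real_),
    density_per_mb = c(ifelse(bases > 0, counts * 1e6 / bases, NA_real_),
                       NA_real_)
  )

  chrom_counts <- setNames(rep(0L, length(clen)), names(clen))
  if (nrow(junctions)) {
    tab <- table(junctions$chrom)
    chrom_counts[names(tab)] <- as.integer(tab)
  }
  chromosomes <- tibble(
    chrom = names(clen),
    n_junctions = as.integer(chrom_counts),
    length = as.numeric(clen),
    density_per_mb = as.integer(chrom_counts) * 1e6 / as.numeric(clen)
  )

  has <- function(cat) map_lgl(mapped$categories, ~ cat %in% .x)
  exclusive <- tibble(
    intron_only = sum(has("intron") & !has("exon")),
    five_utr_only = sum(has("five_utr") & !has("cds") &
                          !has("three_utr") & !has("intron")),
    three_utr_only = sum(has("three_utr") & !has("cds") &
                           !has("five_utr") & !has("intron"))
  )

  structure(
    list(categories = categories, chromosomes = chromosomes,
         exclusive = exclusive, n_junctions = nrow(junctions)),
    class = "context_report"
  )
}

#' @export
print.context_report <- function(x, ...) {
  cat(sprintf("<context_report> %d junction(s)\n", x$n_junctions))
  print(x$categories, n = Inf)
  invisible(x)
}

#' @rdname context_report
#' @param x a `context_report`.
#' @param ... unused.
#' @export
tidy.context_report <- function(x, ...) {
  x$categories
}

#' @rdname context_report
#' @export
glance.context_report <- function(x, ...) {
  dplyr::bind_cols(tibble(n_junctions = x$n_junctions), x$exclusive)
}

#' Fraction of junctions carrying unannotated splice sites
#'
#' A junction breakpoint matches the annotation when it coincides exactly
#' with an annotated exon boundary: `start` with an exon start, `end` with
#' an exon end (this holds on both strands, since the donor/acceptor roles
#' swap but the boundary types do not). The novel fraction is the share of
#' junctions with at least one unannotated breakpoint; with no annotation
#' every junction is novel.
#'
#' @param junctions junction tibble.
#' @param genes gene-model tibble (may have zero rows).
#' @return list with `fraction` and `junctions` (the input plus
#'   `novel_start`, `novel_end`, `is_novel`).
#' @export
novel_splice_fraction <- function(junctions, genes) {
  if (!nrow(junctions)) {
    return(list(fraction = NA_real_, junctions = junctions))
  }
  if (is.null(genes) || !nrow(genes)) {
    junctions$novel_start <- TRUE
    junctions$novel_end <- TRUE
    junctions$is_novel <- TRUE
    return(list(fraction = 1, junctions = junctions))
  }
  starts <- genes %>%
    select("chrom", "exon_starts") %>%
    tidyr::unnest("exon_starts") %>%
    distinct()
  ends <- genes %>%
    select("chrom", "exon_ends") %>%
    tidyr::unnest("exon_ends") %>%
    distinct()
  key_s <- paste(starts$chrom, starts$exon_starts)
  key_e <- paste(ends$chrom, ends$exon_ends)
  junctions$novel_start <- !(paste(junctions$chrom, junctions$start) %in%
                               key_s)
  junctions$novel_end <- !(paste(junctions$chrom, junctions$end) %in%
                             key_e)
  junctions$is_novel <- junctions$novel_start | junctions$novel_end
  list(fraction = mean(junctions$is_novel), junctions = junctions)
}
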