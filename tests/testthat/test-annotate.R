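# hand-built gene models (0-based half-open coordinates)
manual_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                        biotype = "protein_coding",
                        exon_starts = c(1000L, 2000L, 3000L),
                        exon_ends = c(1200L, 2200L, 3200L),
                        cds_start = 1100L, cds_end = 3100L) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, strand = strand, biotype = biotype,
    gene_start = exon_starts[1], gene_end = exon_ends[length(exon_ends)],
    n_exons = length(exon_starts),
    exon_starts = list(exon_starts), exon_ends = list(exon_ends),
    cds_start = cds_start, cds_end = cds_end
  )
}

test_that("feature derivation handles fl flank clipping, UTRs and introns", {
  clen <- c(chr1 = 10000L)
  # gene at the chromosome start: upstream flank clipped to the boundary
  g_edge <- manual_gene(exon_starts = c(300L, 1000L),
                        exon_ends = c(500L, 1200L),
                        cds_start = 350L, cds_end = 1150L)
  f <- derive_features(g_edge, clen, flank = 1000)
  up <- f[f$category == "upstream1k", ]
  expect_equal(c(up$start, up$end), c(0L, 300L))

  # single-exon gene whose CDS is the whole exon: no UTR intervals
  g_one <- manual_gene(exon_starts = 1000L, exon_ends = 1500L,
                       cds_start = 1000L, cds_end = 1500L)
  f1 <- derive_features(g_one, clen)
  expect_equal(sum(f1$category %in% c("five_utr", "three_utr")), 0L)
  expect_equal(sum(f1$category == "intron"), 0L)

  # two exons: exactly one intron, the inter-exon gap
  g_two <- manual_gene(exon_starts = c(1000L, 2000L),
                       exon_ends = c(1200L, 2200L),
                       cds_start = 1100L, cds_end = 2100L)
  f2 <- derive_features(g_two, clen)
  intr <- f2[f2$category == "intron", ]
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end), c(1200L, 2000L))

  # minus-strand gene: 5' UTR is on the high-coordinate side
  g_minus <- manual_gene(strand = "-")
  fm <- derive_features(g_minus, clen)
  five <- fm[fm$category == "five_utr", ]
  three <- fm[fm$category == "three_utr", ]
  expect_true(all(five$start >= 3100L))
  expect_true(all(three$end <= 1100L))
  upm <- fm[fm$category == "upstream1k", ]
  expect_equal(c(upm$start, upm$end), c(3200L, 4200L))
})

test_that("junctions are labelled by breakpoint membership, multi-label allowed", {
  clen <- c(chr1 = 10000L)
  genes <- dplyr::bind_rows(
    manual_gene(),
    manual_gene(gene_id = "lnc1", biotype = "lncRNA",
                exon_starts = c(6000L, 7000L), exon_ends = c(6300L, 7300L),
                cds_start = NA_integer_, cds_end = NA_integer_)
  )
  f <- derive_features(genes, clen)
  j <- tibble::tibble(
    chrom = "chr1",
    start = c(1300L, 500L, 6100L, 9000L),
    end = c(1900L, 600L, 7200L, 9500L),
    strand = "+"
  )
  m <- map_junction_context(j, f)
  # both breakpoints inside intron 1 of g1
  expect_setequal(m$categories[[1]], c("gene", "intron"))
  # 500 bp upstream of g1 (plus strand: upstream is [0, 1000))
  expect_setequal(m$categories[[2]], "upstream1k")
  # inside the lncRNA locus
  expect_true("lncRNA" %in% m$categories[[3]])
  # far from everything
  expect_true(m$intergenic[4])
  expect_length(m$categories[[4]], 0)

  # precedence mode yields one exclusive label
  mp <- map_junction_context(j, f, precedence = TRUE)
  expect_equal(mp$category[1], "intron")
  expect_equal(mp$category[4], "intergenic")
})

test_that("context densities are count per million feature bases", {
  clen <- c(chr1 = 1000000L)
  # one gene spanning 100 kb of genic sequence
  g <- manual_gene(exon_starts = 100000L, exon_ends = 200000L,
                   cds_start = 100000L, cds_end = 200000L)
  f <- derive_features(g, clen)
  j <- tibble::tibble(
    chrom = "chr1",
    start = seq(110000L, 119000L, by = 1000L),
    end = seq(150000L, 159000L, by = 1000L),
    strand = "+"
  )
  rep <- context_report(j, f, clen)
  genic <- rep$categories[rep$categories$category == "gene", ]
  expect_equal(genic$n_junctions, 10)
  expect_equal(genic$feature_bases, 100000)
  expect_equal(genic$density_per_mb, 10 * 1e6 / 1e5)  # 100 per Mb genic
  expect_equal(rep$chromosomes$density_per_mb, 10)

  # empty junction set: all zero counts, no divide-by-zero
  rep0 <- context_report(j[0, ], f, clen)
  expect_true(all(rep0$categories$n_junctions == 0))
  expect_true(all(rep0$chromosomes$n_junctions == 0))

  # junctions on one chromosome leave the other at density zero
  clen2 <- c(chr1 = 1000000L, chr2 = 500000L)
  rep2 <- context_report(j, f, clen2)
  expect_equal(
    rep2$chromosomes$density_per_mb[rep2$chromosomes$chrom == "chr2"], 0
  )
  expect_equal(sum(rep2$chromosomes$n_junctions), nrow(j))
})

test_that("category counts are invariant to junction order and match a brute-force scan", {
  fx <- tiny_sim(seed = 67, n_genes = 5, chrom_length = 40000, n_circ = 4,
                 tissues = c("brain", "heart"))
  clen <- c(chr1 = 40000L)
  f <- derive_features(fx$sim$genes, clen)
  with_test_seed(31, {
    j <- tibble::tibble(
      chrom = "chr1",
      start = sample(0:39000, 30),
      end = integer(30),
      strand = sample(c("+", "-"), 30, TRUE)
    )
    j$end <- j$start + sample(100:5000, 30)
    j <- j[j$end <= 40000, ]
  })
  r1 <- context_report(j, f, clen)
  r2 <- context_report(j[rev(seq_len(nrow(j))), ], f, clen)
  expect_equal(r1$categories, r2$categories)

  # brute-force point-membership scan
  m <- map_junction_context(j, f)
  for (i in seq_len(nrow(j))) {
    pts <- c(j$start[i], j$end[i] - 1L)
    want <- sort(unique(f$category[
      vapply(seq_len(nrow(f)), function(k)
        any(pts >= f$start[k] & pts < f$end[k]), logical(1))
    ]))
    expect_equal(sort(m$categories[[i]]), want)
  }
})

test_that("exclusive-origin counts isolate intron-only and UTR-only junctions", {
  clen <- c(chr1 = 10000L)
  g <- manual_gene()  # exons [1000,1200) [2000,2200) [3000,3200), CDS 1100-3100
  f <- derive_features(g, clen)
  j <- tibble::tibble(
    chrom = "chr1",
    start = c(1300L, 1010L, 3110L, 1050L),
    end = c(1900L, 1090L, 3190L, 1500L),
    strand = "+"
  )
  # j1 intron-only; j2 within 5'UTR (exonic, before CDS); j3 within 3'UTR;
  # j4 starts in 5'UTR but ends in an intron (not exclusive)
  rep <- context_report(j, f, clen)
  expect_equal(rep$exclusive$intron_only, 1L)
  expect_equal(rep$exclusive$five_utr_only, 1L)
  expect_equal(rep$exclusive$three_utr_only, 1L)
})

test_that("the novel splice-site fraction counts unannotated breakpoints", {
  fx <- tiny_sim(seed = 71, n_genes = 4, chrom_length = 30000, n_circ = 4)
  tj <- fx$lib$truth$junctions
  # simulator junctions are built from exon boundaries: fraction 0
  nv <- novel_splice_fraction(tj, fx$sim$genes)
  expect_equal(nv$fraction, 0)

  four <- dplyr::distinct(tj, chrom, start, end, strand)[1:4, ]
  four$start[2] <- four$start[2] + 10L
  nv4 <- novel_splice_fraction(four, fx$sim$genes)
  expect_equal(nv4$fraction, 0.25)
  expect_true(nv4$junctions$is_novel[2])

  # without annotation every junction is novel
  expect_equal(novel_splice_fraction(four, fx$sim$genes[0, ])$fraction, 1)
})

test_that("report accessors expose tidy tables and plots build", {
  clen <- c(chr1 = 10000L)
  f <- derive_features(manual_gene(), clen)
  j <- tibble::tibble(chrom = "chr1", start = 1000L, end = 3200L,
                      strand = "+")
  rep <- context_report(j, f, clen)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_junctions, 1L)
  expect_s3_class(plot_context_density(rep), "ggplot")
  expect_s3_class(plot_chrom_density(rep), "ggplot")
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})
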