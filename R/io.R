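# File-format interfaces. Sequence formats go through Biostrings, feature
# formats through rtracklayer; tibble <-> GRanges conversion lives here so
# the analysis modules stay coordinate-convention-clean (BED: 0-based
# half-open everywhere inside the package).

#' Read / write a genome FASTA
#'
#' @param path file path.
#' @return `read_genome_fasta()` returns a [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @param genome a `DNAStringSet`, named character vector or `sim_genome`.
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  gs <- genome_strings(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(gs), path, width = 70L
  )
  invisible(path)
}

#' Read / write FASTQ read libraries
#'
#' Reads are exchanged as tibbles with columns `read_id`, `seq` and `qual`
#' (Sanger Phred+33). A `tissue` column, when present, is carried into the
#' FASTQ only via the file name; [simulate_reads()] keeps one file per
#' tissue.
#'
#' @param path FASTQ file path.
#' @param tissue optional tissue label attached to every read on input.
#' @return `read_fastq()` returns a tibble of reads.
#' @export
read_fastq <- function(path, tissue = NA_character_) {
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    q <- S4Vectors::mcols(x)$qualities
    qual <- unname(as.character(q))
    # Sanger quality characters are printable ASCII; anything else means
    # the record's quality string did not line up with its sequence
    ok <- vapply(qual, function(s) {
      r <- charToRaw(s)
      length(r) && all(r >= as.raw(33L) & r <= as.raw(126L))
    }, logical(1))
    bad_len <- nchar(qual, type = "bytes") !=
      nchar(unname(as.character(x)), type = "bytes")
    if (any(!ok | bad_len)) {
      stop(sprintf("record `%s` has a corrupt or mismatched quality string",
                   names(x)[which(!ok | bad_len)[1]]))
    }
    list(id = names(x), seq = unname(as.character(x)), qual = qual)
  }, error = function(e) {
    abort(sprintf("malformed FASTQ `%s`: %s", path, conditionMessage(e)))
  })
  tibble(read_id = parsed$id, tissue = tissue, seq = parsed$seq,
         qual = parsed$qual)
}

#' @param reads a read tibble (`read_id`, `seq`, `qual`).
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  assert_reads_tbl(reads)
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

# ---- junction BED ---------------------------------------------------------

junctions_to_granges <- function(junctions) {
  GenomicRanges::GRanges(
    seqnames = junctions$chrom,
    ranges = IRanges::IRanges(start = junctions$start + 1L,
                              end = junctions$end),
    strand = junctions$strand,
    name = if ("name" %in% names(junctions)) junctions$name
           else sprintf("bsj_%05d", seq_len(nrow(junctions))),
    score = if ("support" %in% names(junctions)) junctions$support else 0L
  )
}

granges_to_junctions <- function(gr, extra = character(0)) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    support = if (!is.null(gr$score)) as.integer(gr$score) else NA_integer_,
    strand = as.character(GenomicRanges::strand(gr))
  )
  for (col in extra) out[[col]] <- S4Vectors::mcols(gr)[[col]]
  out
}

#' Read / write back-splice junctions as BED6
#'
#' BED columns are chrom, start (0-based), end (exclusive), name, score
#' (= supporting read count) and strand. Extra columns, such as the tissue
#' column of a simulator truth set, can be declared via `extra_cols`.
#'
#' @param path BED file path.
#' @param extra_cols named character vector of extra column types passed to
#'   [rtracklayer::import()], e.g. `c(tissue = "character")`.
#' @return `read_junctions_bed()` returns a junction tibble (`chrom`,
#'   `start`, `end`, `name`, `support`, `strand`, ...).
#' @export
read_junctions_bed <- function(path, extra_cols = NULL) {
  gr <- rtracklayer::import(path, format = "bed", extraCols = extra_cols)
  granges_to_junctions(gr, extra = names(extra_cols))
}

#' @param junctions junction tibble with at least `chrom`, `start`, `end`,
#'   `strand`; `name`, `support` and `extra_cols` columns are written when
#'   present.
#' @rdname read_junctions_bed
#' @export
write_junctions_bed <- function(junctions, path, extra_cols = NULL) {
  if (is.null(extra_cols)) {
    rtracklayer::export(junctions_to_granges(junctions), path,
                        format = "bed")
    return(invisible(path))
  }
  # BED6 plus extra columns: formatted directly, since the BED dialect has
  # no slot for them
  name <- if ("name" %in% names(junctions)) junctions$name
          else sprintf("bsj_%05d", seq_len(nrow(junctions)))
  score <- if ("support" %in% names(junctions)) junctions$support else 0L
  base <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", junctions$chrom,
                  junctions$start, junctions$end, name, score,
                  junctions$strand)
  for (col in names(extra_cols)) {
    base <- paste(base, junctions[[col]], sep = "\t")
  }
  writeLines(base, path)
  invisible(path)
}

# ---- gene models ----------------------------------------------------------

#' Write gene models as BED12 (+ biotype column)
#'
#' One line per gene: standard BED12 with thickStart/thickEnd holding the
#' CDS span (zero-width at the gene start for non-coding genes) and a 13th
#' column carrying the biotype.
#'
#' @param genes gene-model tibble (see [simulate_genome()]).
#' @param path output path.
#' @export
write_genes_bed12 <- function(genes, path) {
  rows <- pmap(genes, function(gene_id, chrom, strand, biotype, gene_start,
                               gene_end, exon_starts, exon_ends,
                               cds_start, cds_end, ...) {
    sizes <- exon_ends - exon_starts
    rel <- exon_starts - gene_start
    sprintf(
      "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s\t%s",
      chrom, gene_start, gene_end, gene_id, strand,
      ifelse(is.na(cds_start), gene_start, cds_start),
      ifelse(is.na(cds_end), gene_start, cds_end),
      length(sizes),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(rel, collapse = ","), ","),
      biotype
    )
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Read gene models from BED12 (+ biotype column)
#'
#' @param path BED12 path; a 13th `biotype` column is used when present,
#'   otherwise all genes are typed `other`.
#' @return gene-model tibble as produced by [simulate_genome()].
#' @export
read_genes_bed12 <- function(path) {
  has_biotype <- length(strsplit(readLines(path, n = 1L), "\t")[[1]]) >= 13L
  gr <- rtracklayer::import(
    path, format = "bed",
    extraCols = if (has_biotype) c(biotype = "character") else NULL
  )
  blocks <- rtracklayer::blocks(gr)  # absolute 1-based exon ranges
  thick <- gr$thick
  bind_rows(imap(seq_along(gr), function(i, .) {
    b <- blocks[[i]]
    cds0 <- c(IRanges::start(thick)[i] - 1L, IRanges::end(thick)[i])
    no_cds <- cds0[2] <= cds0[1]
    tibble(
      gene_id = gr$name[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      biotype = if (has_biotype) gr$biotype[i] else "other",
      gene_start = GenomicRanges::start(gr)[i] - 1L,
      gene_end = GenomicRanges::end(gr)[i],
      n_exons = length(b),
      exon_starts = list(IRanges::start(b) - 1L),
      exon_ends = list(IRanges::end(b)),
      cds_start = if (no_cds) NA_integer_ else cds0[1],
      cds_end = if (no_cds) NA_integer_ else cds0[2]
    )
  }))
}

#' Write / read gene models as GTF
#'
#' The writer emits one `exon` feature per exon and `CDS` features for
#' protein-coding genes, with `gene_id`, `transcript_id` and `gene_biotype`
#' attributes; the reader accepts any GTF with `exon` (and optionally `CDS`)
#' features and rebuilds the gene-model tibble. UTRs are never read from the
#' file — they are re-derived from exons minus CDS by [derive_features()].
#'
#' @param genes gene-model tibble.
#' @param path GTF path.
#' @export
write_genes_gtf <- function(genes, path) {
  feats <- pmap(genes, function(gene_id, chrom, strand, biotype,
                                exon_starts, exon_ends,
                                cds_start, cds_end, ...) {
    ex <- tibble(chrom = chrom, start = exon_starts + 1L, end = exon_ends,
                 strand = strand, type = "exon",
                 gene_id = gene_id, biotype = biotype)
    if (!is.na(cds_start)) {
      keep <- exon_ends > cds_start & exon_starts < cds_end
      cds <- tibble(
        chrom = chrom,
        start = pmax(exon_starts[keep], cds_start) + 1L,
        end = pmin(exon_ends[keep], cds_end),
        strand = strand, type = "CDS", gene_id = gene_id, biotype = biotype
      )
      ex <- bind_rows(ex, cds)
    }
    ex
  })
  feats <- bind_rows(feats)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = feats$type,
    source = "circfindr",
    phase = ifelse(feats$type == "CDS", 0L, NA_integer_),
    gene_id = feats$gene_id,
    transcript_id = paste0(feats$gene_id, ".t1"),
    gene_biotype = feats$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_genes_gtf
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"gene_id" %in% names(df)) abort("GTF lacks gene_id attributes")
  ex <- df[tolower(df$type) == "exon", ]
  if (!nrow(ex)) abort("GTF contains no exon features")
  cds <- df[toupper(df$type) == "CDS", ]
  bind_rows(lapply(split(ex, ex$gene_id), function(g) {
    g <- g[order(g$start), ]
    cg <- cds[cds$gene_id == g$gene_id[1], ]
    tibble(
      gene_id = g$gene_id[1],
      chrom = as.character(g$seqnames[1]),
      strand = as.character(g$strand[1]),
      biotype = if ("gene_biotype" %in% names(g) &&
                    !is.na(g$gene_biotype[1])) g$gene_biotype[1] else "other",
      gene_start = min(g$start) - 1L,
      gene_end = max(g$end),
      n_exons = nrow(g),
      exon_starts = list(g$start - 1L),
      exon_ends = list(g$end),
      cds_start = if (nrow(cg)) min(cg$start) - 1L else NA_integer_,
      cds_end = if (nrow(cg)) max(cg$end) else NA_integer_
    )
  }))
}

# ---- simulator bundle -----------------------------------------------------

#' Write a complete simulated dataset to a directory
#'
#' Emits `genome.fa`, `genes.bed` (BED12 + biotype), `genes.gtf`, one
#' `reads_<tissue>.fastq` per tissue, the truth set `truth.bed`
#' (BED6 + tissue column, score = planted support), `provenance.tsv`
#' (read origin map) and `config.txt` (flat key=value). Identical
#' configuration and seed reproduce byte-identical files.
#'
#' @param sim a `sim_genome`.
#' @param lib a `sim_reads`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, lib, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_genes_bed12(sim$genes, file.path(dir, "genes.bed"))
  write_genes_gtf(sim$genes, file.path(dir, "genes.gtf"))
  for (tis in unique(lib$reads$tissue)) {
    write_fastq(lib$reads[lib$reads$tissue == tis, ],
                file.path(dir, sprintf("reads_%s.fastq", tis)))
  }
  tj <- lib$truth$junctions
  if (nrow(tj)) {
    write_junctions_bed(
      tj %>% rename(name = "junction_id") %>%
        mutate(name = paste(.data$name, .data$tissue, sep = ".")),
      file.path(dir, "truth.bed"),
      extra_cols = c(tissue = "character")
    )
  } else {
    writeLines(character(0), file.path(dir, "truth.bed"))
  }
  readr::write_tsv(lib$truth$provenance, file.path(dir, "provenance.tsv"))
  write_sim_config(lib$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write / read a simulation configuration as flat key=value text
#'
#' @param config a [sim_config()].
#' @param path text file path.
#' @export
write_sim_config <- function(config, path) {
  keys <- setdiff(names(config), character(0))
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.null(v)) v <- ""
    sprintf("%s=%s", k, paste(v, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- setNames(
    lapply(kv, function(x) if (length(x) > 1L) x[[2]] else ""),
    vapply(kv, `[[`, character(1), 1L)
  )
  split_num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
  sim_config(
    n_chromosomes = split_num(vals$n_chromosomes),
    chrom_length = split_num(vals$chrom_length),
    n_genes = split_num(vals$n_genes),
    exons_per_gene = split_num(vals$exons_per_gene),
    n_circ_per_tissue = split_num(vals$n_circ_per_tissue),
    tissues = strsplit(vals$tissues, ",", fixed = TRUE)[[1]],
    read_length = split_num(vals$read_length),
    junction_support = split_num(vals$junction_support),
    error_rate = split_num(vals$error_rate),
    seed = split_num(vals$seed),
    polyA_mode = vals$polyA_mode == "TRUE",
    anchor_len = split_num(vals$anchor_len),
    exon_length = split_num(vals$exon_length),
    intron_length = split_num(vals$intron_length),
    lnc_fraction = split_num(vals$lnc_fraction),
    tile_step = split_num(vals$tile_step),
    n_junction_pool = if (nzchar(vals$n_junction_pool))
      split_num(vals$n_junction_pool) else NULL,
    low_qual_tail_fraction = split_num(vals$low_qual_tail_fraction),
    paired = vals$paired == "TRUE",
    n_noise_reads = split_num(vals$n_noise_reads)
  )
}
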