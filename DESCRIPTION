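Package: circfindr
Title: Back-Splice Junction Discovery and Tissue Atlas Construction for
    Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects circular RNA back-splice junctions from ribo-depleted
    RNA-seq reads using split-read anchor mapping: 20-nt terminal anchors are
    aligned, anchor pairs in reversed genomic order are extended across the
    read interior under a mismatch budget, and breakpoints are selected by
    the canonical GT/AG splice signal, keeping junctions supported by at
    least two reads. Companion modules provide a synthetic-data generator
    with machine-readable ground truth, quality trimming, a contiguous
    k-mer-seeded aligner that separates linearly explained reads from the
    unmapped remainder, genomic-context annotation with length-normalised
    densities, and multi-tissue integration (tissue-specificity summaries,
    polyA false-positive assessment, junction-set comparison and an exact
    enrichment test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
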