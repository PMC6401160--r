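# circfindr

Split-read discovery of circular RNA (circRNA) back-splice junctions from
RNA-seq, with a simulator that provides ground truth, genomic-context
annotation, and multi-tissue atlas statistics.

## The problem

Back-splicing joins a downstream splice donor to an upstream splice
acceptor, producing a covalently closed circular transcript. Reads
crossing the back-splice junction cannot be aligned contiguously to the
genome: their two ends map in *reversed* genomic order. circfindr is for
researchers building circRNA catalogues from ribo-depleted RNA-seq (bulk,
multi-tissue) who want an auditable implementation of the classic
anchor-based caller together with the downstream bookkeeping a tissue
atlas needs.

The core procedure, for each read left unmapped by contiguous alignment
(ungapped, ≤ 2 substitutions, either strand):

1. align the terminal 20-nt **anchors**; both must be unique best hits;
2. keep pairs in reversed order — head anchor downstream of the tail
   anchor on one chromosome, junction extent within [50, 100000] bp;
3. **extend** across the read interior, enumerating every split offset *b*
   with total mismatches ≤ 2;
4. select the breakpoint whose genomic flanks carry the canonical splice
   signal — `AG | acceptor ... donor | GT` on the plus strand (`AC`/`CT`
   on the forward genome for minus-strand circles); the strand is whatever
   the signal says;
5. report junctions `[start, end)` (BED, 0-based half-open) supported by
   **≥ 2 distinct reads** per library.

Around the caller the package provides: a deterministic synthetic-data
generator (genome + gene models + per-tissue FASTQ + truth BED), Phred-30
trailing-quality trimming, breakpoint-membership annotation against
gene/exon/intron/UTR/±1-kb-flank/lncRNA features with length-normalised
densities, tissue-sharing matrices and summaries, polyA false-positive
assessment, junction-set comparison, and an exact 2×2 enrichment test.

## Worked example

```r
library(circfindr)

cfg <- sim_config(chrom_length = 50000, n_genes = 10,
                  tissues = c("blood", "brain", "heart"),
                  n_circ_per_tissue = 5, seed = 42)
sim <- simulate_genome(cfg)   # genome + gene models, GT/AG at every intron
lib <- simulate_reads(sim)    # per-tissue reads + truth set

res <- run_circ_pipeline(lib$reads, sim)
res
#> <circ_pipeline>
#>   trim   : 404/404 reads kept
#>   linear : 56.4% mapped overall
#>   circles: 9 junction(s) detected

tidy(res)
#> # A tibble: 9 × 10
#>   chrom start   end strand splice_signal support name      support_heart
#>   <chr> <int> <int> <chr>  <chr>           <int> <chr>             <int>
#> 1 chr1   2490  3358 +      GT/AG               2 bsj_00001             2
#> 2 chr1   6791  6989 +      GT/AG               9 bsj_00002             2
#> 3 chr1  11274 11513 -      GT/AG               4 bsj_00003             4
#> # … 6 more rows, plus support_blood / support_brain columns
```

Every detected junction here matches the simulator's truth set exactly —
coordinates, strand and per-tissue support. The trimming stage removed
nothing (synthetic qualities are high by default), 56.4% of reads were
linearly explained and discarded, and the unmapped remainder produced the
nine planted junctions, each with its `GT/AG` splice signal and ≥ 2
supporting reads.

Tissue integration and annotation continue from the same objects:

```r
m <- build_sharing_matrix(attr(res$junctions, "tissue_support"))
sharing_summary(m)
#> <sharing_summary> 9 junction(s) in the union
#>   class          n percent
#> 1 restricted     4   44.44
#> 2 shared         5   55.56
#> 3 shared_all     1   11.11

feats <- derive_features(sim$genes, sim)
context_report(res$junctions, feats, sim)   # counts + densities per Mb

enrichment_test(1869, 670, 14275, 8000)
#> a = 1869, b = 670, c = 14275, d = 8000
#> odds_ratio 1.56, p_value 2.64e-22
```

`sharing_summary()` counts junctions detected in exactly one tissue
(restricted), in ≥ 2 (shared) and in all tissues, as percentages of the
union. `context_report()` normalises per-category junction counts by
feature length (per million bases). `enrichment_test()` is a two-sided
Fisher exact test — here on a gene-level 2×2 of circRNA-forming ability
versus having a cross-species orthologue.

A thin CLI over the same functions is at
`inst/scripts/circfindr-cli.R` (subcommands `simulate`, `trim`, `detect`,
`annotate`, `atlas`, `fpcheck`, `enrich`).

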