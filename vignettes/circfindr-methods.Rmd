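---
title: "Detecting circRNA back-splice junctions with circfindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circRNA back-splice junctions with circfindr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circfindr)
library(dplyr)
```

## The problem and the model

Circular RNAs (circRNAs) arise when a downstream splice donor is joined to
an upstream splice acceptor — *back-splicing* — producing a covalently
closed transcript. In an RNA-seq library, a read crossing the back-splice
junction cannot be explained by any contiguous genomic window: its 5' part
matches a region *downstream* (on the transcribed strand) of where its 3'
part matches. circfindr implements the split-read strategy built on that
signature:

1. **Trim** reads with a 3' trailing-quality rule (Phred cutoff 30).
2. **Discard linearly explained reads**: any read with an ungapped
   end-to-end alignment (either strand, at most 2 substitutions) is not
   circRNA evidence.
3. **Anchor** the remaining reads: the first and last 20 nt are aligned
   exactly and must be unique in the genome (best alignment strictly better
   than any other locus, both strands considered). Pairs in reversed
   genomic order — head anchor downstream of tail anchor on one chromosome
   — are candidate back-splices.
4. **Extend and call**: every split offset of the read interior is scored
   against the two genomic frames implied by the anchors; offsets whose
   total substitution count is within the budget (2) are feasible, and
   among those the breakpoint whose genomic flanks carry the canonical
   splice signal is selected. On the plus strand the forward genome reads
   `AG` immediately before the acceptor start and `GT` immediately after
   the donor end; a minus-strand circle shows `AC`/`CT` at the same
   positions (the reverse complement of `AG`/`GT`). The strand is inferred
   solely from which convention matches.
5. **Aggregate**: candidates are grouped by exact coordinates and strand;
   junctions supported by fewer than 2 distinct reads are dropped.

Coordinates are BED-style throughout: 0-based, half-open; `start` is the
first base of the acceptor exon, `end` one past the last base of the donor
exon.

### Why an ungapped Hamming aligner

The linear-alignment stage exists only to answer a binary question — is
this read contiguously explained by the genome or not? A k-mer-seeded,
ungapped aligner with an explicit mismatch ceiling answers it with exact,
auditable semantics, and its three disjoint seeds (head, centre, tail of
the read) guarantee by pigeonhole that no locus within the 2-substitution
budget is missed for reads of at least three seed lengths (60 nt at the
default `k = 20`). Production aligners' scoring functions are aligner-
specific; translating them into a mismatch ceiling is the one deliberate
approximation in this stage, and it is configurable (`max_mismatch`).
Indels are not modelled anywhere (the simulator emits substitution errors
only), which keeps extension arithmetic exact.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `anchor_len` | 20 | nt | terminal anchor length; the genome index seed length must equal it, so anchor lookup is a single exact query |
| `max_mismatch` | 2 | substitutions | total budget across both sides of the split during extension, and the ceiling for contiguous alignment |
| `min_support` | 2 | reads | junctions below this are discarded; applied per library/tissue by default, with `pooled = TRUE` to apply it to the summed support |
| `min_span`, `max_span` | 50, 100000 | bp | admissible junction extent; excludes trivial self-ligation artefacts and implausible mega-circles |
| `phred_cutoff`, `min_len` | 30, 40 | Phred, nt | 3' trailing trim and the shortest read that still carries two anchors |

Support filtering is per tissue because detection runs per library and
per-tissue catalogues are the unit of downstream sharing analysis; pooled
filtering is available where libraries are technical replicates.

## Numerical and tie-break choices

* **Breakpoint ties.** When several split offsets are feasible, the caller
  iterates them ordered by (mismatch count, offset) and returns the first
  signal-consistent one: fewest mismatches wins, then the leftmost genomic
  breakpoint. This makes output deterministic in shift-ambiguous
  (homopolymer) contexts.
* **Ambiguity.** A read whose two orientations yield different
  signal-consistent junctions is dropped and counted (`n_ambiguous`), not
  guessed at. Likewise, anchors that are not unique best hits are
  discarded.
* **Strand.** Inferred only from the flank dinucleotides. The two
  conventions (`AG`/`GT` vs `AC`/`CT`) cannot both match at one coordinate
  pair, so strand assignment is unambiguous per candidate.
* **Degenerate inputs.** Empty read sets, empty junction sets and
  zero-length feature categories are legal: summaries report zero counts
  and densities are `NA` rather than a division by zero. Reads shorter
  than two anchors are rejected and tallied.
* **Rounding.** Percentages round half away from zero at two decimals
  (`overlap_percent()`), the convention used when comparing against
  published catalogue arithmetic; base R's banker's rounding would differ
  at exact halves.

## What the simulator emulates — and what it does not

`simulate_genome()` builds a uniform-composition random genome and places
non-overlapping gene models with 3–4 exons (150–250 bp each, introns
250–450 bp by default), forcing canonical `GT`/`AG` (strand-appropriately
`CT`/`AC` on the forward strand for minus-strand genes) at every intron
boundary. Protein-coding genes receive a CDS strictly inside their
terminal exons so both UTRs are derivable; a configurable fraction of
genes is typed lncRNA. The default geometry is chosen so that ten genes
always fit on a 50-kb chromosome with 1-kb flanks intact, the standard
study condition used across the test-suite and the acceptance script.

`simulate_reads()` tiles linear reads along every mature transcript (step
50 nt) and implants back-splice junctions chosen from internal exon pairs,
with the junction placed at least one anchor length from both read ends
and both read fragments contained in the joined exons. Implanted junctions
are sampled per tissue from a shared pool (twice the per-tissue count), so
tissue sharing arises naturally. `polyA_mode` emulates a polyA-selected
library: protein-coding transcripts only and zero back-splice reads — the
negative control behind false-positive assessment. Reads default to
high-quality (Phred 35–40) with optional low-quality 3' tails, optional
uniform substitution errors, and optional mates drawn from the linear
backbone (mates add coverage, never junction evidence, because the
detection algorithm is read-wise).

Deliberately **not** modelled: expression-level variation, insert-size
distributions, indels, intron lariats, trans-splicing, adapter
read-through (adapter clipping exists but synthetic reads are clean), and
repeat structure. Passing tests on this generator therefore demonstrate
algorithmic correctness — exact breakpoint recovery, filter behaviour,
negative controls — not robustness to repetitive genomes or gapped
variation, where anchor uniqueness and ungapped extension would be the
limiting factors on real data.

## Annotation and atlas conventions

Junction-to-feature assignment is by **breakpoint membership**: a junction
is counted in every category containing `start` or `end - 1`. Whole-span
overlap would count every intron and exon a large circle merely spans,
which is not what a junction catalogue means. Multi-labelling is retained
(a breakpoint in a UTR is also exonic and genic); an optional precedence
mode (CDS > 5'UTR > 3'UTR > exon > intron > flanks) yields exclusive
labels. Exclusive-origin counts isolate junctions whose breakpoints are
intronic but never exonic, or in one UTR class but in neither the CDS, the
other UTR, nor an intron. UTRs are always re-derived from exons minus the
CDS span, never trusted from annotation files, making BED12 and GTF input
equivalent. Densities are counts per million bases of the reduced
(non-redundant) feature length, and per-chromosome densities per million
chromosome bases.

Junction identity across tissues and pipelines is **exact**
(chromosome, start, end, strand). Published catalogues are intersected on
coordinates, and fuzzy matching silently merges distinct circles; a
`slop` option exists for cross-caller comparisons that differ by
convention. "Tissue-restricted" means nonzero support in exactly one
tissue; "shared" means two or more.

The enrichment surface (`enrichment_test()`) is a two-sided Fisher exact
test; the reported odds ratio is the sample odds ratio `(ad)/(bc)` with a
degeneracy flag for zero cells, which is the directly interpretable
quantity for 2x2 catalogue contrasts (the conditional-MLE estimate is not
needed at these table sizes). Orthologue tables are consumed as plain
two-column files; no remote queries are made.

## Problem sizes and verification

The test-suite verifies each stage against an independent brute-force
oracle on small instances: a sliding Hamming scan at every position and
strand for the aligner, an exhaustive split-offset/string-search enumerator
for the caller (genomes up to 5 kb), subset enumeration for sharing
summaries, and hypergeometric enumeration for the exact test (margins up
to 30). End-to-end recovery is checked on the standard study condition —
one 50-kb chromosome, 10 genes, 5 tissues, 8 implanted junctions per
tissue at support 2–5, error-free reads — where detection must achieve
100% recall at exact coordinates with zero false junctions, and a
polyA-mode library must yield zero calls. These sizes keep every check
fast while exercising both strands, shared junctions and all filters; the
same conditions are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Anchor alignment is exact-match: a sequencing error inside an anchor
  loses that read (the mismatch budget applies to the interior extension
  only). At support >= 2 this costs sensitivity, not specificity.
* No gapped alignment; small indels near a breakpoint shift the inferred
  coordinates or drop the read.
* The caller reports junctions, not internal circle structure or
  circular-to-linear expression ratios.
* Repeat-rich regions defeat anchor uniqueness by design: non-unique
  anchors are discarded rather than rescued.
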