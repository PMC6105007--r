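---
title: "Methods: from barcoded reads to a quality-controlled count matrix"
author: "scpreproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from barcoded reads to a quality-controlled count matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`scpreproc` preprocesses barcoded single-cell RNA-seq data: raw
paired-end FASTQ files in which each read pair carries a cell barcode
and (usually) a unique molecular identifier (UMI), plus a BAM of
transcript alignments produced by any external aligner, are turned
into a genes-by-cells matrix of molecule counts with per-stage QC
statistics, automatic detection of low-quality cells, and a
standalone HTML report. The pipeline is modular: every stage reads
and writes plain files in a run directory and can be re-run
individually.

Alignment itself is deliberately out of scope. Any spliced aligner
that outputs BAM and preserves read names can be used between the
reformatting and tagging stages; the read-name header scheme (below)
is how barcode information survives that external step.

## Read reformatting

The read structure (`read_structure()`) declares, with 0-based
offsets, where the barcode segment(s) and the UMI sit within the
pair, which mate carries the UMI and which carries the cDNA. This
accommodates CEL-seq/MARS-seq plate layouts, 10X/Drop-seq droplet
layouts, and single-read layouts where the transcript is the residual
suffix of the same read after trimming. Segments must fit inside each
processed read; a read too short for the declared structure is
rejected and counted (`removed_too_short`) rather than silently
truncated.

Barcode and UMI are moved into the read name as
`"<barcode>_<umi>#<original name>"`. The encoding is lossless and
parseable because barcodes and UMIs are drawn from the DNA alphabet,
which contains neither separator. Two optional filters run at this
stage:

* **Quality**: the pair is rejected when more than
  `max_low_quality_bases` (default 1) bases of the combined
  barcode + UMI region fall below `min_barcode_quality` (default
  Phred 20). A corrupted barcode cannot be demultiplexed reliably, so
  filtering here is cheaper than mis-assigning reads later.
* **Complexity**: the transcript is rejected when its longest
  single-base run exceeds `max_mononucleotide_fraction` (default 0.9)
  of its length, or when it is more than 90% `N`. This removes
  non-informative repetitive sequences, typically polyA run-through.

Both thresholds are design choices of this package, made
configurable because protocols and base callers differ. The stage's
four counters always sum to the number of input pairs.

## Feature assignment

The annotation (GTF/GFF3) is compiled into a binned interval index:
each chromosome is divided into non-overlapping fixed-width bins
(default 10 kb) and each bin lists the merged exon intervals and gene
bodies overlapping it, so classifying an alignment only inspects the
bins its blocks touch. The bin width trades memory against lookup
speed and never changes results — the test suite asserts identical
assignments at 500 bp, 10 kb and 1 Mb.

Coordinates are 0-based half-open internally; GTF's 1-based inclusive
intervals are converted once at parse time, which keeps every overlap
computation in a single convention.

Assignment rules, applied to the aligned reference blocks (CIGAR
`M`/`=`/`X`, so spliced alignments contribute each block separately):

* unmapped flag set → `unaligned`;
* reference name starts with the spike-in prefix (default `ERCC-`) →
  `ercc`, with the contig as gene id;
* overlap of at least `min_overlap` (default 1 bp) with exons of
  exactly one gene → `exon`; of more than one gene → `ambiguous`;
* otherwise, overlap with at least one gene body → `intron`;
* otherwise → `aligned_elsewhere`.

The default is unstranded; `stranded_mode` restricts exon hits to the
matching strand for stranded protocols. Each primary alignment
receives tags `BC` (barcode), `OX` (UMI), `GE` (gene) and `YS`
(status); secondary and supplementary alignments are skipped and
counted separately, so the six status counts always partition the
primary alignments.

## Barcode detection and demultiplexing

For plate protocols the user supplies the designed whitelist; for
droplet protocols `detect_barcodes()` discovers it: barcode sequences
are counted (by default over the first 5 million reads, a depth at
which every real cell of a 1,000–5,000-cell library is observed),
then walked in descending count order, folding any barcode within
hamming distance 1 of a more abundant accepted barcode into it —
near-duplicates at trace abundance are sequencing errors, not cells.
Either the top *n* barcodes or all barcodes above a count cutoff are
returned. The recommendation is a deliberately relaxed selection
(more barcodes than expected cells): cell quality is judged later
from multiple QC metrics, not from read counts alone. Counting
aggregates before ranking and ties break lexicographically, so
detection is independent of read order. Hamming rather than full
edit distance is used because barcodes are fixed length.

Demultiplexing matches each read's `BC` tag against the whitelist:
exact matches short-circuit; otherwise the unique entry at minimal
hamming distance within `max_mismatch` (default 1) wins. Equidistant
minimal matches leave the read unassigned (`ambiguous`) — assigning
arbitrarily would contaminate cells. Each cell's `exon`/`ercc` reads
are appended to its CSV table (`gene_id,umi,position`); the four
matching counters sum to the reads processed.

## UMI deduplication and counting

Within each (cell, gene) pair, the distinct UMI sequences and their
read counts are collected and collapsed greedily: processing UMIs in
descending read-count order (ties lexicographic), a UMI is folded
into an already-retained UMI when the two are within hamming distance
`max_hamming` (default 1) **and** the retained UMI has more than
twice the candidate's reads. The strict inequality means an
exactly-double count does not merge. The rationale is that erroneous
UMIs produced by sequencing errors typically carry one or two reads,
far fewer than their parent molecule.

Two further decisions make the pass well defined. Counts are frozen
at their input values, and folds only target retained UMIs, so no
chains (A into B into C) can form; and deduplication ignores the
mapping position, which is kept in the tables for audit only —
fragmentation makes position an unreliable molecule key for 3' end
protocols. The raw UMI multiset of every (cell, gene) is exported
alongside the matrix so that network-based correction methods can be
applied externally when PCR error rates are high; such methods are
out of scope here.

With `has_umi = FALSE` (Smart-seq-class protocols) entries are read
counts and the UMI column holds a constant placeholder.

## Quality control

Per-cell metrics aggregated across stages include total reads,
molecules, genes detected, the percentage of reads per mapping
status, mitochondrial and ribosomal count percentages, and — when
spike-ins are annotated — spike-in recovery, defined here as the
fraction of annotated control species detected with at least one
molecule. Ribosomal genes default to symbols matching `Rps`/`Rpl`
(case-insensitive, overridable); mitochondrial genes are those on the
configured mitochondrial contigs.

`detect_outliers()` flags low-quality cells in three stages on
z-scored metrics (standardization makes results invariant to affine
rescaling of any metric and improves conditioning; a ridge of
1e-8 times the mean diagonal is added before inverting any
covariance):

1. **Pre-filter.** Squared Mahalanobis distances against the pooled
   mean/covariance; cells beyond the chi-square quantile at
   `extreme_quantile` are removed before model fitting and flagged.
   This stage exists to keep gross extremes from distorting the
   mixture fit, so its quantile (default 0.999) is stricter than the
   reporting confidence `conf`: the routine outlier calling is the
   job of stage 3, and using `conf` here as well would double-count
   the nominal error rate.
2. **Mixture.** A Gaussian mixture with up to `comp` components
   (model and component number selected by BIC via `mclust`) is
   fitted to the remaining cells. Components whose means are below
   the best component's on the majority of signed metrics (molecules
   and genes count positively; mitochondrial/ribosomal percentages
   negatively) are flagged wholesale. On clean data BIC selects one
   component and this stage is a no-op; `comp = 1` skips it
   entirely. `comp = 2` or `3` suits droplet data where a sizeable
   poor-quality population is expected.
3. **Within-component distance.** Distances are recomputed among the
   best component's cells and those beyond the chi-square quantile at
   `conf` (default 0.99) are flagged.

Under a single well-conditioned Gaussian the flagged fraction
calibrates near `1 - conf` (the test suite checks 0.5–2% at
`conf = 0.99` over 2,000 cells), and a 10% population shifted by
3 SD is recovered with sensitivity and specificity around 0.99.

## Synthetic data generators

The generators exist so every stage is testable against known truth
without downloads, and their defaults are the study conditions of the
test suite: 24 cells, 20 two-exon genes plus an overlapping pair, 2
mitochondrial genes and 8 spike-in contigs; molecules per (cell,
gene) drawn Poisson with mean 5 (mean 2 for spike-ins); PCR
duplication uniform on 1–20; barcodes of length 8 kept at pairwise
hamming distance at least 4 (so one error is uniquely correctable and
two errors never reach another barcode's neighbourhood); true UMIs
within a (cell, gene) kept at pairwise distance at least 3; UMI error
variants injected at hamming distance 1 with fewer than half their
parent's reads, so greedy deduplication can recover molecule counts
exactly — which the tests assert. Noise reads realise intronic,
intergenic, ambiguous and unmapped placements. This yields roughly
35,000 reads, a size chosen so the full suite runs in a few minutes
on one CPU.

What the generators do **not** emulate — and therefore what passing
tests do not show about real data: realistic transcript sequences and
expression programs, ambient RNA and empty droplets, doublets,
chimeric PCR products, indel sequencing errors (substitutions only),
and barcode error rates beyond one substitution per read. The
outlier-detector simulations draw QC metrics directly from Gaussian
mixtures, which matches the detector's model; real QC distributions
are heavier-tailed, and calibration on real data should be checked
against the pairwise QC plots.

## Numerical and degenerate-input choices

* Ranking ties anywhere (barcode counts, UMI counts) break
  lexicographically, making every stage deterministic and
  order-independent.
* A fold candidate with several eligible targets goes to the nearest,
  then most abundant, then lexicographically smallest.
* Cells with zero assigned reads keep a QC row with zero metrics;
  mapping percentages for such cells are reported as zero.
* Constant or collinear QC metrics make the covariance singular; the
  detector stops with an explicit message rather than guessing, and
  the automatic metric selection simply drops constant columns.
* A non-convergent mixture fit falls back to a single component with
  a warning.
* The report reads only the stage CSV files, renders missing stages
  as explicit notices, and never writes into the pipeline outputs.

## Limitations

Multi-mapped reads are not rescued (secondary alignments are
skipped); transcript-isoform quantification is out of scope; UMI
collapse is per gene, so UMIs shared across genes are counted per
gene; and the greedy fold is intentionally simpler than
network-based UMI correction — the raw UMI export is the escape
hatch when that matters.
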