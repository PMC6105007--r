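# scpreproc

Preprocessing of barcoded single-cell RNA-seq data: from raw FASTQ
files and an aligner-produced BAM to a UMI-deduplicated gene count
matrix, per-stage QC statistics, automatic low-quality-cell
detection, and a standalone HTML report.

## Who this is for

Labs generating 3' end scRNA-seq data with cell barcodes and unique
molecular identifiers (UMIs) — CEL-seq, MARS-seq, Chromium 10X,
Drop-seq — or non-UMI protocols such as Smart-seq, who want a
modular, scriptable R workflow between the sequencer and downstream
analysis. Read alignment itself is delegated to any aligner that
produces BAM and preserves read names; everything around it is
handled here.

## What it computes

**Demultiplexing.** Barcode and UMI bases are trimmed into the read
name (`"<barcode>_<umi>#<name>"`), survive external alignment there,
and are recovered into BAM tags (`BC`, `OX`). Each observed barcode
is assigned to the whitelist entry at minimal hamming distance
*d* ≤ `max_mismatch`; ties are left unassigned. For droplet data the
whitelist itself is detected by counting barcode sequences and
folding hamming-1 neighbours of more abundant barcodes into them.

**Gene assignment.** Chromosomes are split into fixed-width bins,
each listing the exons and gene bodies overlapping it; an alignment's
CIGAR blocks are classified as
`exon` / `ambiguous` / `intron` / `aligned_elsewhere` /
`unaligned` / `ercc` (spike-in contigs) with precedence
ercc > exon > ambiguous > intron > elsewhere.

**Molecule counting.** Within each (cell, gene), UMIs are collapsed
greedily in descending read-count order: UMI *v* folds into retained
UMI *u* when

> hamming(*u*, *v*) ≤ 1  and  count(*u*) > 2 · count(*v*)

(strict — erroneous UMIs carry few reads relative to their parent
molecule). The matrix entry is the number of retained UMIs; raw UMIs
are exported for external correction methods.

**Cell QC.** Per-cell metrics (log molecules, genes detected,
mitochondrial/ribosomal percentages, spike-in recovery) feed a
three-stage outlier detector: a Mahalanobis pre-filter against the
pooled covariance (χ² quantile), a Gaussian mixture (up to `comp`
components, BIC-selected) whose dominated components are flagged
wholesale, and a final Mahalanobis step within the best component at
confidence `conf` (default 0.99). Under multivariate normality
d² = (x−μ)ᵀΣ⁻¹(x−μ) ~ χ²(k), which is what the thresholds use.

## Worked example

Everything below runs on synthetic data with known ground truth — no
downloads needed.

```r
library(scpreproc)

sim <- simulate_experiment("demo_data", seed = 1)
cfg <- pipeline_config(out_dir = "demo_run",
                       bam = sim$bam, r1 = sim$r1, r2 = sim$r2,
                       annotation = sim$gtf,
                       whitelist = sim$whitelist,
                       structure = sim$structure,
                       comp = 1, seed = 1)
res <- run_pipeline(cfg)
#> [trim-barcode] 35632/35632 read pairs kept
#> [exon-map] 27921 exon, 3894 ercc, 1273 intron reads
#> [demultiplex] 35632 exact, 0 mismatch, 0 unmatched, 0 ambiguous
#> [count] 30 genes x 24 cells, 3070 molecules
#> [qc] 0/24 cells flagged as outliers
#> [run] complete: demo_run
```

The log follows the reads through the stages: all 35,632 simulated
pairs pass the quality/complexity filters, 27,921 land on exons and
3,894 on spike-in contigs, every barcode matches its cell exactly
(the fixture injects no barcode errors), and deduplicating the
~35k reads leaves 3,070 molecules. No cell is an outlier in this
clean simulation.

```r
res$counts$matrix[1:4, 1:4]
#>           cell_001 cell_002 cell_003 cell_004
#> ERCC-0001        1        3        1        1
#> ERCC-0002        1        4        5        4
#> ERCC-0003        1        0        0        1
#> ERCC-0004        2        2        2        4

head(res$qc[, c("cell_id", "molecules", "genes_detected",
                "pct_mapped_exon", "pct_mito")], 3)
#>    cell_id molecules genes_detected pct_mapped_exon pct_mito
#> 1 cell_001       115             22        79.48911 9.565217
#> 2 cell_002       128             22        74.75000 6.250000
#> 3 cell_003       148             22        81.12642 5.405405
```

The deduplication rule on its own:

```r
dedup_umis(c(AAAAAT = 12L, AAAAAA = 3L, TTTTGG = 5L))
#> $molecules
#> [1] 2
#>
#> $retained
#> AAAAAT TTTTGG
#>     15      5
#>
#> $merge_map
#>     from   into count
#> 1 AAAAAT AAAAAT    12
#> 2 TTTTGG TTTTGG     5
#> 3 AAAAAA AAAAAT     3
```

`AAAAAA` (3 reads) is one mismatch from `AAAAAT` (12 reads > 2 × 3),
so it is folded; `TTTTGG` is four mismatches away and stays a
separate molecule. `demo_run/report.html` is the self-contained QC
report; `demo_run/gene_count.mtx` / `.csv` the matrix.

A command-line wrapper with per-stage subcommands is included at
`inst/cli/scpreproc-cli.R`.

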