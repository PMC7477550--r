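# diurnal

Circadian rhythm detection and reprogramming analysis for
multi-condition gene-expression time courses.

A stimulus — a drug challenge, a genotype, a diet — can rewire a
tissue's circadian transcriptome: control-condition oscillators lose
rhythmicity, *de novo* oscillators appear, and shared oscillators shift
phase or amplitude. `diurnal` implements the full analysis chain for
detecting and characterizing such reprogramming from FPKM-like
gene × sample matrices sampled across the day (default: 6 zeitgeber
times every 4 h, 3 replicates), plus a promoter-scanning enrichment
layer that nominates candidate transcription-factor drivers of the
condition-specific rhythmic programs.

## What it computes

**Rhythm detection** — a from-scratch implementation of the JTK_CYCLE
family of nonparametric tests. Each gene's series *x* is scored against
reference cosine patterns ref(t) = cos(2π(t − t₀ − L)/P) over a grid of
periods P ∈ [20, 28] h and lags L, with the tied Kendall statistic

S = Σ_{i<j} sign(x_i − x_j) · sign(ref_i − ref_j)

Replicates are exact ties in the reference. p-values are **exact and
conditional on both tie patterns**: a Harding-style product of Gaussian
binomials when the data are tie-free, and an exact dynamic program over
tie groups otherwise — both verified against exhaustive permutation
enumeration. The minimum p over the grid is Bonferroni-adjusted by the
number of period/lag combinations (18 for the default design); a gene
is rhythmic at adjusted p < 0.01. Reported per gene: adjusted p,
period, lag, peak phase (ZT h), Kendall tau, and a cosinor (OLS)
amplitude.

**Preprocessing** — Dixon's Q outlier test (Dean–Dixon 95% critical
values; Q = gap/range, at most one replicate pruned per gene ×
timepoint) and the "consistently low expression" filter (all values
< 1 FPKM in every compared condition), with the enrichment background
defined as every gene with any positive value.

**Reprogramming comparison** — Venn partition of two conditions'
rhythmic sets (exclusive / common / exclusive, with union percentages),
phase histograms (radar-plot data), amplitude-change taxonomy of
common oscillators (higher / lower / equal at a ±5% tolerance), and
phase-sorted row-z-scored heatmap matrices.

**TFBS enrichment** — per TF, a one-sided Fisher/hypergeometric test of
quality-filtered binding sites (BBLS > 1, site FDR < 0.25; TFs with
more than 50000 surviving sites excluded as degenerate) in strand-aware
promoter windows (−10000/+2000 of the TSS) of a rhythmic set against
the expression background; ranking by −log10 p; a cross-condition
meta-analysis flagging condition-exclusive TFs; target-set construction
combining motif sites in −3000/+1000 windows with ChIP peak support;
and generic GMT gene-set enrichment with BH correction.

**Synthetic data** — a seeded generator emulating the 2-genotype ×
2-treatment, 6 × 3 design with planted oscillator classes (including a
ZT7-clustered de-novo set), multiplicative lognormal noise, injected
single-replicate outliers, and a matched motif/peak annotation in which
a focal TF's sites concentrate in de-novo promoters — so every stage
is testable against known ground truth with no external data.

## Worked example

```r
library(diurnal)

cfg <- pipeline_config(simulation = list(), seed = 8)  # 2000 genes, 4 conditions
res <- run_pipeline(cfg)
res
#> pipeline_result
#>   conditions: WT_saline, WT_cocaine, KO_saline, KO_cocaine
#>   rhythmic genes: WT_saline=304, WT_cocaine=305, KO_saline=112, KO_cocaine=110
#>   condition-exclusive TFs: PPARG (WT_cocaine)

res$report$comparisons[["WT_saline_vs_WT_cocaine"]]$partition
#> rhythm_partition: WT_saline vs WT_cocaine, union 507 genes
#>   WT_saline-only 202 (40%), common 102 (20%), WT_cocaine-only 203 (40%)

res$report$comparisons[["WT_saline_vs_WT_cocaine"]]$phase_hist$exclusive_b
#>   0   2   4   6   8  10  12  14  16  18  20  22
#>   0  23  33 106  32   6   1   1   0   1   0   0
```

Reading the output: of the 507 genes rhythmic in either WT condition,
202 cycle only under saline (rhythm lost upon treatment), 102 in both,
and 203 only under cocaine — the de-novo program, whose phase histogram
peaks in the ZT [6, 8) bin, exactly where the generator planted it. The
meta-analysis flags the planted focal TF (here named PPARG) as
exclusively enriched in the treated condition's rhythmic promoters
(−log10 p = 10.3 vs ≤ 1.7 for every decoy), and its ChIP-supported
target set recovers planted targets with precision 1.0. The knockout
conditions show no de-novo program — their rhythmic sets stay at
baseline — mirroring a genotype that blocks the treatment response.

## Package layout

| Path | Contents |
| --- | --- |
| `R/timecourse.R`, `R/io_bed.R` | validated readers/writers: expression TSV, BED6 sites/peaks/TSS, GMT |
| `R/preprocess.R` | Dixon Q pruning, low-expression filter, background |
| `R/jtk.R` | scan grid, tied Kendall S, exact conditional nulls, per-gene and matrix-level scans |
| `R/compare.R` | set partition, phase histograms, amplitude taxonomy, heatmap matrices |
| `R/enrichment.R` | promoter windows, TFBS Fisher enrichment, meta-analysis, target sets, GMT enrichment |
| `R/synthetic.R` | simulation spec, time-course generator, outlier injection, motif/peak annotation |
| `R/pipeline.R` | configuration (YAML round-trip) and the orchestrated pairwise pipeline |
| `vignettes/circadian-reprogramming.Rmd` | the methods vignette: model, assumptions, design choices, limitations |

See the vignette for the statistical details and the reasoning behind
every default.
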