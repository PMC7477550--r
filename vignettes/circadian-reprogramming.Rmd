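---
title: "Detecting circadian reprogramming: methods and design choices"
author: "diurnal package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian reprogramming: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diurnal)
```

## The problem

A stimulus (a drug, a diet, a genotype) can rewire which genes in a
tissue oscillate over the day: rhythms present under control conditions
can be lost, new ("de novo") oscillators can appear, and common
oscillators can change phase or amplitude. `diurnal` implements the
complete analysis chain for such multi-condition expression time
courses: nonparametric rhythm detection per condition, set-level
comparison of the rhythmic programs across conditions, and a
promoter-scanning enrichment layer that asks which transcription
factors plausibly drive the condition-specific oscillators.

The expected experimental design is FPKM-like, nonnegative gene x
sample matrices, one per condition, sampled at `T` zeitgeber times over
one cycle (default ZT 3, 7, 11, 15, 19, 23 — every 4 h) with a small
number of replicates per timepoint (default 3).

## Rhythm detection

Rhythmicity is scored with a from-scratch implementation of the
JTK_CYCLE family of rank tests.  For each candidate period `P` and lag
`L` on a grid, the reference pattern

```
ref(t) = cos(2 * pi * (t - t0 - L) / P)
```

is evaluated at each sample's timepoint (`t0` = first sampling time),
so replicates at one timepoint are exact ties in the reference.  The
gene's series `x` is compared to `ref` with the tied Kendall statistic

```
S = sum over pairs (i, j) of sign(x_i - x_j) * sign(ref_i - ref_j)
```

with tied pairs contributing zero.  The period grid holds the integer
multiples of the sampling interval inside the 20–28 h circadian window;
lags step by the sampling interval in `[0, P)`.  For the default design
this is periods {20, 24, 28} with {5, 6, 7} lags — 18 combinations.

### Exact conditional null distribution

The p-value for each combination is exact and conditional on the tie
patterns of both vectors: the distribution of `S` under uniform random
pairing of the data multiset against the reference multiset.  Two code
paths compute it:

* **One side tie-free** (the usual case — FPKM values are continuous):
  `S` is a linear image of the number of inversions across reference
  tie groups, whose generating function is a product of Gaussian
  binomials (Harding's construction) — each factor the exact
  Mann–Whitney null for merging one tie group into its predecessors.
* **Ties on both sides** (e.g. after FPKM rounding, or degenerate
  series): an exact dynamic program over reference tie groups whose
  state is the multiset of data values consumed so far.  Exponential in
  the worst case, but only invoked when the data genuinely carry ties,
  and cached across genes by tie-pattern signature.

Both paths are checked against exhaustive permutation enumeration in
the test suite.  The reported p is two-sided, `P(|S| >= |S_obs|)`; the
minimum p over the grid is Bonferroni-multiplied by the number of
combinations and capped at 1.  The plain Bonferroni factor over all
(P, L) pairs is used; other JTK builds group lag hypotheses
differently, so the factor is a configurable argument.

### Selection, phase, amplitude

The reported combination is the argmin of p, ties broken toward the
smaller period and lag.  Two consequences of this rule are worth
stating plainly:

* An anticorrelated match (`S < 0`) is the cosine at lag `L + P/2`; the
  scan re-anchors there, reporting the shifted lag and positive tau.
  Without this re-anchoring, antiphase combinations (whose |S| ties the
  matched one) would produce 12-h phase errors.
* Because the exact conditional null differs between tie patterns, the
  20- and 28-h references — whose half-period offsets fall between the
  24-h lag grid — can legitimately attain the minimum p for
  oscillators whose phase lies off the 4-h grid.  On planted 24-h
  oscillators the selected period is therefore 24 h for the large
  majority of on-grid phases and the **modal** selected period, not a
  per-gene guarantee.  Phase recovery is unaffected (median error well
  under 1 h in the test conditions).  This period smearing is a known
  property of short, coarsely sampled designs.

Phase is reported as the reference peak time, `(t0 + L) mod 24` ZT
hours.  Amplitude is the absolute cosine coefficient of an ordinary
least-squares cosinor fit at the selected period and phase — a
deliberate, documented substitute for JTK's Hodges–Lehmann-style
estimator; downstream analyses only use amplitude *ratios*, which are
consistent across reasonable estimators.  Because the test is
rank-based, p-values are invariant under any strictly monotone
transform of the data; whether FPKMs are logged upstream therefore
does not affect detection, only the amplitude scale (amplitudes here
are on the raw input scale).

A gene is called rhythmic when its adjusted p is strictly below the
cutoff (default 0.01).

## Preprocessing

**Replicate outliers.**  Per gene and timepoint with at least three
usable replicates, Dixon's Q test (`Q = gap / range` for the more
isolated extreme) removes at most one replicate when Q exceeds the
Dean–Dixon one-sided 95% critical value (0.941 at n = 3).  The test
runs on raw values; at n = 3 it is scale-equivariant enough that this
choice is minor, but it is fixed and documented.  Removed samples are
masked, not deleted, so the rank test conditions on the exact remaining
tie structure.  The per-gene-per-timepoint reading is the only one
consistent with pruning "up to one replicate per timepoint" of
transcriptomic replicates.

**Low expression.**  A gene leaves the analysis when *all* its
non-missing values in *every* compared condition fall below the floor
(default 1, FPKM units); a mean-based alternative is exposed as a
switch.  The enrichment background keeps every gene with any positive
value anywhere — a strict superset of the analysis set.

## Comparing rhythmic programs

`partition_rhythm_sets` decomposes two conditions' rhythmic sets into
exclusive/common/exclusive with percentages of the union (rounded
half-up, matching the reporting convention of published Venn counts);
per-input totals are also reported so either convention — union
percentages or per-condition totals — can be read off.
`phase_histogram` bins fitted phases into half-open bins over
`[0, 24)`.  `classify_amplitude_change` classes common oscillators by
the amplitude ratio with an "equal" band of ±5% by default — published
reports of such taxonomies state no tolerance, so this convention is a
config knob, not an estimate.  `heatmap_matrix` produces the
phase-sorted, row z-scored matrix of timepoint means (constant rows map
to zeros) that phase-ordered heatmaps display.

## Promoter TFBS enrichment

For each TF, genes are classed by presence of at least one
quality-filtered binding site (BBLS > 1, site FDR < 0.25, both strict)
overlapping (>= 1 bp) the strand-aware promoter window — default
−10000/+2000 around the TSS, reflected for − strand genes so upstream
extends toward larger coordinates.  All intervals are 0-based
half-open.  The 2×2 table contrasts the study set against
background-minus-set (disjoint cells — the only construction giving a
valid exact test) and is scored with the one-sided hypergeometric tail.
TFs with more than 50000 filtered sites are excluded as degenerate
motifs before testing.  TFs are ranked by −log10 p without
multiple-testing correction across TFs, matching how such rankings are
conventionally reported; BH correction is available in the generic
gene-set enrichment, which serves the pathway-analysis role on local
GMT collections.

The cross-condition meta-analysis flags a TF as exclusive to condition
c when p(c) <= alpha_tf (default 0.01) and p > alpha_tf everywhere
else.  No published threshold exists for this call, so both the
threshold and a top-k-by-rank alternative are implemented; the
threshold rule is the default.  Target sets combine motif evidence in
the narrow −3000/+1000 window with ChIP peak support; intersection of
the two evidence types is the default (union is a flag), since
"combining" motif and ChIP data is most conservatively read as
requiring both.

## The synthetic-data generator

`simulation_spec`/`generate_timecourse` emulate the study design the
package targets: 4 conditions (2 genotypes × 2 treatments), 6
timepoints × 3 replicates, 2000 genes.  Genes split into four classes —
control-exclusive oscillators (10%), common oscillators (5%), de-novo
oscillators present only in the treated condition (10%, phases
clustered at ZT7 with 1.5 h circular-normal jitter), and flat genes.
Values follow `mu_g * (1 + a * cos(2*pi*(t - phi)/P)) * exp(eps)`:
multiplicative lognormal noise (sd 0.1) because FPKM noise scales with
the mean and the detector is rank-based anyway; baselines are lognormal
(meanlog log 10, sdlog 1); relative amplitudes are uniform on
[0.3, 0.8] — a convention, since no effect-size distribution is
published for real amplitudes; the planted period is fixed at 24 h
because the 4-h, 6-point design cannot resolve finer structure.
Occasional single-replicate outliers (rate 0.02, factor 8) exercise the
Dixon pruning.  The motif layer gives each gene a non-overlapping 20-kb
territory on one synthetic chromosome (TSS at the centre, random
strand), plants one focal-TF site in the narrow promoter window of each
focal-target gene (a de-novo gene with probability `p_in` = 0.5, any
other gene with `p_out` = 0.05), scatters 20 decoy TFs uniformly (2000
sites each), draws BBLS from Exponential(mean 2) and site FDR from
Uniform(0, 0.5) (so ~30% of sites pass the default quality filter), and
covers focal sites of true targets with ChIP peaks with probability
0.9.  All randomness flows from one root seed; identical specs are
bit-reproducible.

What the generator does *not* emulate — count noise, unequal library
sizes, batch effects, correlated genes, non-sinusoidal waveforms,
realistic motif co-occurrence — bounds what passing tests show: they
validate the statistical machinery under the stated model, not
performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Reference cosine values are rounded to 9 decimals so symmetric
  timepoints tie exactly.
* Exact ties in the data contribute 0 to S and enter the tie pattern;
  no jitter is added.
* Constant or all-missing series report p = 1, tau = 0, amplitude = 0
  rather than erroring.
* `tau = S / max|S|`, with the maximum computed for the actual tie
  patterns by aligning the sorted multisets.
* A zero replicate range makes Dixon's Q undefined; nothing is pruned.
* Constant heatmap rows z-score to all zeros.
* Percentages are rounded half-up (not banker's rounding) for report
  parity.

## Problem sizes

The test suite validates the exact null against full permutation
enumeration for series up to n = 8 (200 random tie-pattern pairs),
measures the false-positive rate on 2000 pure-noise genes, and runs the
recovery and enrichment checks on the generator's 2000-gene,
4-condition default — sizes chosen to exercise the study-scale code
paths while keeping a full run in tens of seconds.

## Known limitations

* Period estimation is limited to the grid; 20/28 h selections on true
  24-h oscillators occur for off-grid phases (see above).
* The general both-sides-tied null DP is exact but can be slow for
  pathological tie patterns (many large tie groups on both sides) at
  n >> 20.
* Enrichment is gene-level (has >= 1 site), not site-count-level.
* No differential-rhythmicity test (DODR-style) is provided; the
  comparison layer is descriptive, as in the analyses it mirrors.
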