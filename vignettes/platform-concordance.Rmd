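---
title: "Comparing microRNA qPCR platforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing microRNA qPCR platforms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcompare)
```

## The problem

Quantifying a circulating microRNA signature on a high-throughput qPCR
platform trades reaction volume for throughput. A 96-well plate runs 5 µl
reactions; microfluidic cards, through-hole arrays and integrated fluidic
circuits run 1 µl, 33 nl and 15 nl. The number of template molecules that a
reaction receives is, at limiting dilution, Poisson-distributed with mean

λ = concentration × reaction volume / dilution factor,

so a miRNA that lands ~80 copies into a 5 µl reaction lands ~1 copy into a
15 nl reaction of the same material. At λ = 1 roughly 37% of reactions
receive no template (e⁻¹), 37% one copy and 18% two — stochastic dropout
plus integer-copy jitter that no amount of pre-amplification removes,
because a reaction that starts with zero copies stays at zero. `ctcompare`
implements the replicate-level, cross-platform and cluster-level statistics
used to quantify these effects against a gold-standard platform, and a
simulator of the whole measurement process so the pipeline can be validated
against known ground truth.

## Replicate variability and fidelity

Replicate groups are (platform, run, sample, miRNA) cells (runs can be
pooled on request; within-run precision and between-run reproducibility are
distinct questions, so the default keeps them apart). Per group we report:

- mean CT, standard deviation (sample, n−1 denominator: replicates are a
  sample of the measurement process), CV% = 100·sd/mean computed **on the CT
  scale** — plausible published replicate CVs of a few percent only make
  sense on that scale, not on linearised abundance — and range = max − min;
- the expression tier of the group mean: ultra-high (CT < 10), high
  [10, 20], moderate (20, 30], low (> 30). Printed tier conventions often
  leave hundredth-cycle gaps (10.01–20.00, 20.01–30.00); we close them so
  every positive CT has exactly one tier.

**Fidelity** at cutoff c ∈ {1, 2, 3} cycles is the percentage of scorable
replicate groups with range strictly below c ("differed by less than" is a
strict inequality; a range exactly equal to the cutoff fails it). Its
complement is the deviation from fidelity. Two policies govern dropouts: the
default `fail_all` counts any group containing an undetermined replicate as
exceeding every cutoff — a dropout is a worse-than-8-fold discordance — and
`exclude` scores only determined replicates. Groups are the scoring unit
(range over all replicates), not replicate pairs; with n = 2 replicates the
two conventions coincide, and group scoring is the stricter, more
interpretable choice at n > 2.

Tier-stratified variation summarises the replicate range per (platform,
tier): on nanoliter platforms the low tier's median range exceeds the high
tier's, because at small λ the copy count itself varies.

## Cross-platform concordance

CT/CRT values from different platforms are not directly comparable
(different chemistries, pre-amplification depth, dilution and detection
thresholds shift the scale), so each platform is standardised: replicates
are collapsed to the cell mean (arithmetic mean of determined CTs, runs
pooled — one value per cell is what a cross-platform scatter needs), cells
not determined on *every* compared platform are dropped
(pairwise-complete per compared pair, which is what makes 42 shared miRNAs ×
4 samples = 168 pairs per comparison when nothing drops out), and
z = (ct − mean)/sd within the platform. Standardisation is idempotent and
removes any affine rescaling of the raw CTs, so the statistics depend only
on the rank-scale geometry of the data. Z-scoring is done over all matched
cells per platform; standardising within sample type (cellular vs serum)
would be an alternative when the two matrices have very different dynamic
ranges, but the pooled default keeps one interpretable scale per platform.

Concordance between a reference platform (x) and a comparison platform (y)
is ordinary least squares of y on x plus Pearson r; the regression slope
measures dynamic-range **compression** (slope < 1) or expansion (> 1)
against the ideal slope of 1, and R² = r² for simple OLS. Unweighted OLS
with the gold standard on x matches the benchmarking convention; orthogonal
(Deming) regression and Bland–Altman limits are deliberate non-goals.

## Cluster concordance

Per platform, the miRNA × sample matrix of z-scored cell means is filtered
— miRNAs with more than 15% missing cells, pooled across all platforms, are
excluded (this absorbs assays unreadable on one platform without
hard-coding names) — and remaining gaps are imputed with the row (miRNA)
mean, the least structured single-value choice. Rows are clustered with
Ward's minimum-variance criterion on Euclidean distances (`hclust`,
`ward.D2`, monotone fusion heights). The cluster count uses the **Mojena
stopping rule**: scanning the n−1 fusion heights α₁ ≤ … ≤ αₙ₋₁, the first
merge j with αⱼ > mean(α) + k·sd(α) marks the significant fusions, and the
partition just before it — n − j + 1 clusters — is selected (k = 1 when no
height exceeds the bound). The constant defaults to 1.25, the classical
recommendation, and is configurable; larger constants can only decrease the
selected k. The assignment is then refined by k-means initialised at the
Ward-cut centroids — deterministic, no random restarts, so the published
dendrogram-plus-k-means workflow is exactly reproducible; if k-means ever
empties a cluster the Ward partition is kept and the trace records it.

Two partitions are compared by matching comparison clusters to reference
clusters one-to-one so as to maximise total shared membership (exhaustive
over label permutations, exact up to 8 clusters); a miRNA is concordant iff
its comparison cluster maps to its reference cluster, and the
misassignment percentage is reported. The looser "at least two comembers"
reading is available as `mode = "literal"`; the optimal matching is the
default because it is label-invariant and gives 0% for any relabelling of
the same partition.

## Signature profiles

A biomarker panel (≥ 3 miRNAs, caller-fixed axis order) is rendered as a
radar polygon: axes at equal angles 2π/n, per-axis radius the cell-mean CT
(optionally inverted to max − CT, since lower CT means more abundant; raw
CT is the default display convention). The polygon area is
½·sin(2π/n)·Σᵢ rᵢ·rᵢ₊₁ (cyclic) — invariant under rotation and reversal of
the axis order and homogeneous of degree 2, so doubling every radius
quadruples the area. Profile comparisons report both areas, their ratio and
the Pearson correlation of matched axes ("shape"); a constant profile has
undefined shape correlation and is flagged rather than silently dropped.

## The simulator

The simulator is the package's testbed: it generates CT tables with known
ground truth under the volume-physics model.

1. **Partition**: copies ~ Poisson(λ), λ = concentration × volume /
   dilution, independently per reaction.
2. **Amplify**: deterministic pre-amplification gain, N = copies ×
   (1+E)^cycles with efficiency E ∈ (0, 1]. (Stochastic early-cycle
   amplification would add bias amplification; the deterministic gain is the
   simplest model that preserves the dropout structure, since zero copies
   remain zero.)
3. **Detect**: ct = ct₁ − log(N)/log(1+E) + 𝒩(0, σ_platform) + run shift,
   where ct₁ is the CT of one effective copy; at E = 1 each doubling of
   template lowers CT by exactly one cycle. Reactions with zero copies, or
   CT beyond the max-cycle detection limit, are undetermined.
4. **Run shifts**: one Gaussian offset per (platform, run), emulating
   systematic between-run drift.

All randomness flows from one master seed through named substreams
(partition, noise, run shift, per platform), so identical configurations are
byte-identical and each component can be perturbed independently.

### Default study conditions

Four platforms: 5 µl (ViiA7-like, 12 pre-amp cycles, 1:40), 1 µl
(TLDA-like, 12, 1:40), 33 nl (OpenArray-like, 12, 1:40) and 15 nl (Dynamic
Array-like, 16, 1:10). 42 miRNAs (including 3 housekeeping controls) × 4
samples (2 cellular, 2 serum) × 2 runs × 4 replicates — within the 2–8
replicate range typical of such studies. Efficiency 0.95, single-copy CT
44, detection limit 40 cycles, run-shift sd 0.5 cycles. The truth profile
plants four abundance/pattern groups — cellular-enriched, serum-enriched,
ubiquitously high, uniformly low — giving the clustering pipeline a
recoverable 4-group structure and the low group λ ≈ 0.1–7 per nanoliter
reaction, the regime where Poisson dropout bites. Platform noise sds (0.10,
1.10, 0.33, 1.15 cycles) were set once by back-solving published median
replicate CVs for these four platform classes (0.6%, 8.3%, 2.1%, 9.5%) at
their observed median CTs; they encode the empirical fact that platform
noise is not purely a volume effect (the 1 µl card class is noisier than
the 33 nl array class).

### What the simulator does and does not emulate

It reproduces: volume-ordered dropout (dropout ≈ e^(−λ), λ ∝ volume),
volume/noise-ordered replicate CV and fidelity, tier-dependent replicate
range, run-to-run shifts, and a clusterable cross-sample structure. It does
**not** model instrument-specific threshold chemistry: with a single global
single-copy CT, the 15 nl platform's simulated CTs sit slightly *above* the
5 µl platform's, whereas real relative-threshold (CRT) instruments can
report systematically lower values. Nor does it model RT/pre-amp chemistry,
primer-pool incompatibilities (missing assays are just missing data to the
pipeline), or stochastic pre-amplification. Passing tests therefore
demonstrate that the *pipeline* measures what it claims under a faithful
Poisson-dropout model — not that any real platform will show a particular
absolute CV or fidelity value.

## Numerical choices and degenerate inputs

- Strict inequalities in fidelity; undetermined groups fail all cutoffs by
  default.
- z-scoring requires ≥ 3 matched cells and nonzero variance; constant
  platforms are an error, not a silent NaN.
- Mojena with a single merge treats sd as 0 (k = 1 unless that one height
  exceeds its own mean, which it cannot).
- k-means is Ward-seeded and deterministic; empty-cluster degeneracies fall
  back to the Ward partition and are flagged in the trace.
- Cluster matching is exhaustive and exact for ≤ 8 clusters (8! ≈ 4×10⁴
  assignments), ample for expression-tier-scale cluster counts.
- Radar area ratio of two zero-area profiles is defined as 1; a zero-area
  denominator with nonzero numerator is an error.
- Identical replicates give CV = range = 0 exactly; identical matrix rows
  merge at height 0.

## Problem sizes

The default synthetic study is 4 × 2 × 4 × 42 × 4 = 5,376 measurements and
runs the full pipeline in a few seconds; the validation suite uses 10⁵
draws for the Monte-Carlo/analytic comparison, 100 seeded replicates for
planted-partition recovery, and n ≤ 7 instances for the exhaustive Ward
oracle. These sizes make every check cheap to re-run while keeping
Monte-Carlo error well inside the asserted margins.

## Known limitations

Normalisation to housekeeping miRNAs (ΔCT/ΔΔCT), amplification-efficiency
estimation from dilution series, Deming regression, Bland–Altman agreement,
bootstrap cluster stability and sequencing-based discovery are out of
scope. The signature panel is always a user input — the package never
hard-codes a particular biomarker set.
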