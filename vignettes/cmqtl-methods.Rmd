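---
title: "Mapping cell-morphological QTLs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cell-morphological QTLs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphoqtl)
```

## The problem

Image-based profiling (Cell Painting) measures thousands of per-cell
morphology features — shape, intensity, texture, granularity, radial
distribution — across cellular compartments. When profiles are collected
for a cohort of genotyped donor cell lines, each feature becomes a
quantitative trait and one can ask which genetic variants shape cell
morphology: cell-morphological QTLs (cmQTLs). morphoqtl implements the
full analysis path from a single-cell feature table and donor genotypes
to rare-variant burden associations, common-variant scans, and a power
projection for future sample sizes, together with a synthetic-data
generator that provides ground truth for every stage.

## Profile processing

**Cell and trait QC.** Cells missing more than 5% of trait measurements
are removed (`qc_cells`); traits that are blocklisted, never measured,
or non-variable are removed (`qc_traits`, variance tolerance `1e-12` —
anything below is numerically constant).

**Context split.** Cells with zero touching neighbors are *isolate*
cells; cells with one or more are *colony* cells. Morphology responds to
local crowding, so every downstream analysis runs separately per
context.

**Aggregation and INT.** Traits are averaged over the retained cells of
each well, then gaussianized by rank-based inverse normal transformation
across all wells jointly (i.e. across plates): value
$\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with average ranks for ties.
We use the Blom offset $c = 3/8$, the most common convention in QTL
work; the offset is a parameter. INT runs on the well matrix *before*
pseudo-bulking; applying it after donor averaging is a sensitivity
question users can probe by calling the functions in the other order.

**Composite traits.** Morphology features are massively redundant. A
greedy procedure selects representatives so that no retained pair has
$|r| \ge 0.9$ in *any* context: neighbor counts (pairs at or above the
threshold) are summed across the colony and isolate donor-level
correlation matrices, the max-count trait becomes a retained hub, the
hub and all its above-threshold neighbors leave the pool, and the count
recomputation repeats. Ties go to the lexicographically smallest trait
name so the selection is deterministic. We use absolute correlation
(anti-correlated pairs are just as redundant; a signed mode exists). The
post-condition — every retained pair below threshold in every matrix —
is asserted inside the function on every call.

**Pseudo-bulk.** Donor-level values are means over the donor's wells;
the donor's neighbor-count covariate is the cell-weighted mean.

## Variance decomposition

Each gaussianized well-level trait is decomposed with a linear mixed
model (REML, via lme4):

```
trait ~ age + PC1..PC4 [+ neighbors, colony only]
        + (1|disease) + (1|source_tissue) + (1|sex)
        + (1|plate) + (1|well) + (1|on_edge) + (1|donor)
```

"Well" is the well-position label shared across plates (row/column
identity); a per-plate-unique well effect would be confounded with the
residual at well-level data. Random-component fractions come directly
from the REML variances. The fixed-term contribution is the variance of
the fitted fixed-effect predictor over the observed design; it is
apportioned to the fixed groups (age; ancestry PCs; neighbors)
proportionally to their individual predictor variances, so that all
fractions sum to exactly 1 even when covariates are correlated.

Significance per component uses likelihood-ratio tests on ML fits.
A variance component's null value sits on the boundary of its parameter
space, so the reference distribution is the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (p = 1 when the statistic is 0);
fixed groups use an ordinary $\chi^2$ LRT with df equal to the removed
columns. P-values are Bonferroni-corrected for the number of traits
analyzed.

**A calibration caveat.** The realized variance of a random factor with
$L$ levels fluctuates around its nominal value with relative error
$\approx\sqrt{2/(L-1)}$ — for a 7-plate study that is ±58%, and no
estimator can do better than the realized value. Recovery checks in the
test suite therefore calibrate on many-level factors (well position,
donor), where nominal and realized variances agree; plate-level
fractions on real-shaped designs should be read as descriptive of the
realized batch effects, not as precise estimates of a generative
parameter.

## Genotype processing

**Common-variant QC**, in order: structural filters (autosomal,
biallelic, unique position, indels ≤ 5 bp, FILTER = PASS), removal of
donors with >10% genotype missingness, then MAF ≥ 5%, variant
missingness ≤ 5%, and exact Hardy–Weinberg p ≥ 1e-5. MAF is computed on
observed genotypes. The HWE test is the exact conditional test computed
by full enumeration of heterozygote counts given the allele counts, with
probability-ordering two-sided p-values; the test suite verifies it
against an independent enumeration for every configuration up to n = 50.

**LD pruning** is greedy within sliding windows, in two
parameterizations: r² > 0.1 in 50 kb windows sliding by 10 kb (before
GRM/PCA) and r² > 0.2 in 50-variant windows shifting by 5 (before the
effect-size mixture fit). Within a window the member of the worst
offending pair with the smaller MAF is removed (tie: later position),
mirroring the convention of the standard pruning tools. Long-range-LD
exclusion regions (BED, 0-based half-open) are dropped first.

**GRM and ancestry PCs.** The genetic relatedness matrix is the
standard normalized cross-product
$G_{jk} = \frac1M \sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ with
per-variant mean imputation of missing dosages; the top 20 eigenvectors
scaled by $\sqrt{\lambda}$ are the ancestry PCs (sign convention:
largest-magnitude loading positive). The first four PCs enter all
association models.

**Burden collapsing.** Qualifying rare variants are autosomal, PASS,
called in >95% of donors, observed MAF < 1%, and annotated HIGH or
MODERATE impact. Each donor is coded carrier/non-carrier of any
qualifying allele per gene; genes below the carrier floor
`ceiling(0.02 * n_donors)` are dropped (6 at 297 donors — `ceil` is
chosen because 0.02 × 297 = 5.94 must round *up* to match a floor of
"at least 2% of donors"). At desk-scale cohorts a planted gene can
legitimately fall out of testing when its observed MAF drifts above 1%;
this is the filter working as specified, not a power failure.

## Association

Both arms use the same ordinary-least-squares engine: trait on predictor
(carrier indicator, or additive dosage 0/1/2) with covariates age, sex,
ancestry PCs 1–4, plate indicators, and — colony context only — the
donor's mean neighbor count. Plate enters as fixed categorical
indicators rather than a random intercept: at donor level with seven
plates this is the fixed-effect absorption equivalent of a
linear-regression (non-mixed) scan engine. The engine residualizes
predictors and traits on the covariates through one QR decomposition
(Frisch–Waugh–Lovell), which is algebraically exact OLS and lets a full
genes × traits scan run as two matrix products; the suite checks it
against a textbook QR reference at 1e-10. Predictors collinear with the
covariates are skipped with a diagnostic; donors with missing dosage are
dropped per variant. P-values are two-sided t with residual df.

Multiple testing is pure Bonferroni, as is standard for these scans:
0.05/(traits × genes) for the burden arm (2.2e-8 at 246 × 9105) and
5e-8/traits for the common arm (2e-10 at 246). Calibration diagnostics:
genomic inflation $\lambda$ = median observed $\chi^2_1$ / 0.4549, and
permutation nulls that shuffle donor labels on the trait side (burden
validation) or the genotype side (common validation) and re-run the full
scan with a seeded RNG. $\lambda$ on a few hundred correlated tests is
median-noise dominated (sd ≈ 0.1), so calibration bands in the tests are
applied to pooled p-values.

## Effect-size mixture and power projection

Concatenated scan z-scores ($\hat\beta/\mathrm{se}$ across all traits)
are modeled as a zero-mean Gaussian scale mixture,
$z \sim \sum_k \pi_k\, \mathcal N(0,\, N\tau^2_k + 1)$, where $\tau^2_k$
are variances of standardized true effects and the +1 is sampling
variance at the fitting sample size. Component 1 is pinned at
$\tau^2 = 0$ (the null spike); K defaults to 4. We fit by EM — for this
no-LD marginal model the likelihood is an exact Gaussian scale mixture,
so EM is a transparent, testable maximum-likelihood estimator (a
methodological substitution for the Fourier-regression machinery of the
original effect-size-mixture estimators, which buys nothing here because
the synthetic variants carry no LD). Multiple seeded restarts;
convergence at |ΔlogL| < 1e-8; the likelihood trace is stored and tested
for monotonicity. After convergence, components whose marginal variance
is within 5% of the null's ($N\tau^2 < 0.05$) are folded onto the spike:
below that resolution non-null mass is not identifiable, and without the
fold a pure-null fit can split its weight across cosmetically distinct
but statistically identical components.

Projection: at each sample size $N$ the expected significant fraction is
$\sum_k \pi_k \cdot 2\Phi(-z^*/\sqrt{N\tau^2_k + 1})$ with $z^*$ the
normal quantile of the significance threshold (computed with
`lower.tail = FALSE` to avoid cancellation at thresholds like 2.2e-8);
the null spike contributes exactly $T p^*$ false positives. Expected
counts are monotone in $N$ by construction. On weak-signal input the fit
collapses to the spike — the expected, and observed, behavior of an
underpowered common-variant arm.

## The synthetic-data generator

The generator emulates the features of the real study design that the
pipeline's statistics depend on: 297 donors on 7 plates (each donor on
exactly one plate, so plate and donor are partially confounded exactly
as in a one-plate-per-line layout), 8 wells per donor on a 16 × 24 grid
with edge flags, ~2.5% isolated cells (neighbor counts 0 vs
1 + Poisson(3)), genotypes in Hardy–Weinberg proportions with common
MAF in (0.05, 0.5) and rare MAF below 0.01 grouped into genes with
HIGH/MODERATE annotations, and an additive per-cell trait model
(plate + well + donor + residual Gaussians scaled to requested variance
fractions, default plate 0.60 / well 0.05 / donor 0.17 / residual 0.18,
mirroring the dominant-plate, moderate-donor structure of real
morphology data). Planted effects add β × carrier (or β × dosage) to the
donor component, in total-SD units. A single base seed drives named RNG
substreams per stage (genotypes, profiles, metadata, missingness), so
adding one stage never perturbs another and identical configs are
byte-identical.

What it does **not** emulate: LD between variants (variants are
independent; a block-correlated generator exists only to exercise the
pruners), real CellProfiler feature semantics (traits are abstract
indices), pixel-level imaging artifacts, cell-cycle or density
covariance structure, and relatedness between donors. Passing tests
therefore demonstrate the *statistical machinery* — calibration,
recovery, determinism — not robustness to every pathology of real
images. Per-well retained cell counts and the trait count are not
design-determined; defaults (120 cells/well, 40 traits) are desk-scale
choices and every test sets its own.

One consequence of well averaging worth knowing: the cell-level residual
shrinks by the number of cells per well at well level, so requested
*cell-level* fractions are only directly recoverable from well data when
wells hold one cell. Calibration tests use exactly that configuration;
study-shaped simulations instead check structure qualitatively (plate
dominant, donor moderate) — which is also how the per-trait fractions on
real data should be read.

## Numerical choices

* INT requires ≥2 distinct values per trait (constants must be removed
  by QC first); means are computed over observed entries only, and the
  missing sentinel is `NA`, never numeric 0.
* The exact HWE p sums probabilities ≤ the observed configuration's with
  a 1 + 1e-12 relative guard against ties lost to floating point.
* LD pruning resolves the largest-r² offending pair first, so the
  greedy path is order-deterministic.
* Monomorphic variants are skipped with a warning in the GRM and
  silently in the scan (they carry no information).
* Mixed-model non-convergence is flagged on the result, never silently
  zeroed; singular fits (a variance estimated at 0) are expected under
  the null and allowed.
* EM weights renormalize every step; τ² is clamped at 0.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while every calibration check keeps
its statistical meaning: cohorts of 60–300 donors, 6–12 plates, 1–12
cells per well, 5000 null burden tests for type-I calibration, 1e5
z-scores for mixture recovery, exhaustive HWE enumeration to n = 50,
200-feature fixtures for the brute-force comparisons, and ten
independent end-to-end studies for planted-effect recovery. Full-scale
quantities that depend on the real restricted-access data (per-trait
variance percentages, specific hit genes) are not reproducible from
synthetic data and are used only as qualitative structure targets.

## Known limitations

* The variance model assumes independent Gaussian components; real
  plate effects can be heavy-tailed or drift within batches.
* Burden regression treats carrier status as fixed; it does not model
  variant-level heterogeneity within a gene (all qualifying variants are
  exchangeable).
* The projection assumes test exchangeability when partitioning the
  concatenated statistics across traits, and inherits any
  miscalibration of the fitted mixture.
* With ~300 donors the common-variant arm is intrinsically underpowered;
  its mixture fit collapsing to the null spike is informative about
  power, not about biology.
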