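---
title: "Dendritic spine morphometry and episodic memory: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dendritic spine morphometry and episodic memory: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecog)
```

## The scientific question

Episodic memory in very old adults varies widely even at comparable levels
of Alzheimer-type pathology. One candidate substrate is the morphology of
dendritic spines — the micron-scale protrusions that house excitatory
synapses — rather than their number: spine head diameter scales with
postsynaptic density size and AMPA-receptor content, i.e. with synaptic
strength. `spinecog` implements a complete analysis pipeline for asking
whether a spine trait (density, length, head diameter, volume) measured in
a cortical region improves the prediction of an episodic-memory composite
beyond amyloid-plaque burden, tangle burden, sex and age — and a synthetic
cohort generator that emulates the statistical structure of such a study so
every stage is testable without restricted human data.

The pipeline has five stages, run per region (a temporal-cortex-style
region, "BA37", where the head-diameter effect lives, and a premotor-style
region, "BA6", used as a negative control):

1. **Morphometry**: measure and classify each reconstructed spine.
2. **Feature aggregation**: one row of spine traits per case and region.
3. **Discovery**: LASSO over the four traits on a random half of cases,
   with the penalty chosen by repeated cross-validation.
4. **Validation**: nested linear models compared by leave-one-out
   cross-validated MSE on the held-out half, with bootstrap MSE intervals.
5. **Screen**: full-cohort Spearman correlations between all spine features
   and cognition/pathology scores under Storey q-value FDR control.

## Morphometry definitions

All lengths are micrometres. For a spine reconstructed as an ordered
backbone polyline with a per-point diameter profile:

* **Length** is the curvilinear backbone length from the insertion point to
  the most distal point (sum of consecutive Euclidean distances); it can
  never be shorter than the straight-line chord.
* **Head diameter** is the breadth of the head at its widest
  cross-section. Operationally the profile is split at its global minimum
  strictly between insertion and tip: the **neck diameter** is that minimum
  (the insertion point is excluded) and the head diameter is the maximum
  over the distal portion. Profiles with fewer than three points cannot be
  split; they are flagged degenerate and fall back to the global max/min.
  Pipelines starting from pre-measured head/neck columns bypass this rule.
* **Volume** is the voxel count of the reconstructed spine object times the
  volume of a single voxel.
* **Density** is spines per 10 um of dendrite: `10 * count / length`.

Classification uses the established threshold set (head-to-neck ratio 1.1,
length-to-head ratio 2.5, mushroom head 0.35 um, filopodium length 3.0 um),
applied in this order:

1. head/neck > 1.1 **and** head > 0.35 um: **mushroom**;
2. head/neck < 1.1 and (length/head > 2.5 **or** head < 0.35 um):
   **filopodia** if length > 3.0 um, otherwise **thin**;
3. everything else: **stubby**.

The quoted rules use strict inequalities on both sides of 1.1, so a ratio
exactly at 1.1 — and a ratio above 1.1 with a small head — matches no rule.
We route all unmatched cases to stubby, the only class the rule set never
defines positively, and flag them (`classify_residual_flag()`) rather than
guessing which rule a particular tracing package would evaluate first. The
length/head ratio uses the total curvilinear length, since length is
defined once for the spine.

## The synthetic cohort generator

`generate_cohort()` emulates the cohort structure this kind of study
samples: `n_cases = 128` donors aged 90.53 ± 6.06 years; 8–12 neurons per
case (uniform over the range — the distribution within the range is a
choice, not an assertion about any real cohort); one dendritic segment of
20–40 um per neuron; about 5 spines per 10 um; a class mix of 45% thin,
30% stubby, 20% mushroom, 5% filopodia, typical of aged cortical basal
dendrites. Per-class head diameters and lengths are truncated lognormals
and head-to-neck ratios uniform on class-specific bands at or above 1
(see `class_geometry_defaults()`); the thresholds constrain the classes,
not their distributions, so these shapes are invented, documented and
user-overridable. Every draw is rejection-sampled until the measured spine
classifies as requested, so the generator and classifier agree by
construction — a property the tests verify by measuring constructed
geometry back.

Between-case variation enters through per-case lognormal factors on head
diameter (`hd_case_sdlog = 0.10`), length (0.12), density (0.15) and
apparent volume (`vol_case_sdlog = 0.20`). The volume factor deserves a
note: volume is modelled as a spherical head plus cylindrical neck,
quantized to voxels, and is therefore strongly coupled to head diameter
within a case. Bright-field Golgi volume is, however, the least reliable of
the four measurements — axial smear and staining depth vary per
preparation — so a per-case reliability factor on apparent volume is part
of what realistic data look like. Without it, case-mean volume would be an
almost deterministic copy of case-mean head diameter, which no optical
dataset exhibits.

Covariates: sex is coded 0 = female, 1 = male (recorded in the case-table
metadata), with 35% males as in typical community brain-donation cohorts.
NP (neuritic plaque) and NFT (tangle) scores are truncated normals on a
semiquantitative 0–3-style scale, with a male shift of −0.35 pathology
units on both — males carry less pathology, and this is the reason sex
belongs in the prediction models. The episodic-memory composite (a
Z-score-scale quantity) is generated linearly:

memory = b0 + b_hd * meanHD_region + b_np * NP + b_nft * NFT +
b_sex * male + noise,

using each case's *realized* mean head diameter, with region-specific
`beta_hd` (default 8 memory units per um for the BA37-like region, 0 for
the BA6-like region), `beta_np = -0.35`, `beta_nft = -0.30`,
`beta_sex = -0.15`, `noise_sd = 0.35`. The effect scale was fixed once by a
design-stage power argument: one case-level SD of mean head diameter is
about 0.04 um, so `beta_hd = 8` moves memory by ~0.32 units, roughly 0.55
of its total SD — a signal detectable in a 63-case discovery half without
being overwhelming, which is the regime the analysis is designed to probe.
Exactly `n_missing = 3` cases receive at least one missing value among
{NP, NFT, memory}, missing at random, so the complete-case filter removes
exactly three cases (128 to 125, split 63/62).

Randomness is organized as one sub-stream per (case, neuron), seeded by a
stable hash of the cohort seed and the indices, so enlarging the cohort
never shifts draws for existing cases. `detail = "geometry"` additionally
realizes every spine as a 5-point backbone whose measurements reproduce the
drawn values exactly; `detail = "measures"` skips that construction — the
round-trip tests establish the two are equivalent, and replicate
experiments use the faster mode.

What the generator does **not** emulate: image stacks or tracing error
(beyond the lognormal volume noise), staining artifacts, spatial
correlation of spines along a dendrite, item-level cognitive tests,
longitudinal decline, or any real cohort's joint covariate distribution.
Passing recovery tests on these cohorts therefore shows the *estimators*
do their job under the assumed generative model — not that any particular
biological effect size is true.

## Discovery: LASSO with repeated cross-validated penalty selection

On the discovery half, the four spine traits (and only those — covariates
enter at validation) predict the memory composite under the L1-penalized
objective

(1/2n) * sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j |b_j|,

with the intercept unpenalized and predictors standardized to unit
population SD (coefficients are reported back on the original scale). The
normalization makes lambda comparable across sample sizes, and the grid is
100 log-spaced values from lambda_max = max_j |x_j'(y - ybar)|/n (the
smallest penalty at which every coefficient is exactly zero) down to
lambda_max * 1e-4. The path is fit by cyclic coordinate descent with
covariance updates and warm starts (compiled kernel; tolerance 1e-7 on the
maximum standardized coefficient change, at most 1e5 sweeps). Correctness
is pinned by tests: OLS at lambda = 0, exact zeros at lambda_max,
closed-form soft-thresholding on orthonormal designs, KKT conditions along
the path, and agreement with an independent penalized-regression
implementation.

Penalty selection repeats K-fold cross-validation (K = 10) with reshuffled
folds, records the per-repeat CV-MSE minimizer, and takes the median over
repeats — the lower median when the repeat count is even, so the selected
value is always a grid point actually chosen by some repeat. The analysis
scripts use 1000 repeats; the replicate experiments in the tests and the
acceptance script use 25–100 repeats, a problem-size choice that leaves the
selection distribution's median essentially unchanged. Whether
cross-validation should minimize MSE or apply the 1-SE rule is genuinely
open; we default to the minimizer (`rule = "min"`) and expose
`rule = "1se"`. The choice matters for sparsity under the null: with
pure-noise traits, lambda-min over-selects — roughly half of null cohorts
still admit one small coefficient — while the 1-SE rule shrinks all four
traits to zero in the clear majority of replicates. Both behaviours are
asserted in the tests.

## Validation: nested models under leave-one-out cross-validation

On the validation half, candidate linear models (full; full without age;
pathology + sex + head diameter; pathology + sex; pathology + head
diameter; pathology + sex + length) are compared by LOOCV MSE, computed via
the hat-matrix identity e(-i) = e_i / (1 - h_ii), which the tests show
equals n explicit refits to 1e-10. LOOCV is the right tool here because of
its low bias and variance for comparing nested models at this sample size.
Two fit summaries are reported, because they answer different questions: an
R² on pooled out-of-fold predictions (1 − SSE_pred/SST) and the Pearson
correlation between observed and predicted values.

Uncertainty on each model's MSE comes from a case-level bootstrap: resample
whole cases with replacement, recompute the full LOOCV MSE per replicate
(B = 1000 in the workflow), and take the percentile interval at 90%
coverage. Residual resampling would be the alternative; we resample cases
because the case is the sampling unit. A known limitation, measured during
development with a coverage simulation on a well-specified linear model
(n = 40, 200 outer replicates): these percentile intervals *undercover* —
about 80% empirical coverage at 90% nominal — because the LOOCV-MSE
distribution is right-skewed and duplicated cases make resampled LOOCV
slightly optimistic. The intervals are useful as stability summaries, not
as calibrated frequentist intervals, and the tests assert their defined
behaviour (percentile of the replicate distribution, determinism, Monte
Carlo stability) rather than a coverage guarantee.

## The correlation screen

Over the full filtered cohort (n = 125), every spine feature (overall and
per class) is correlated with every cognition/pathology score by Spearman's
rho — the Pearson correlation of mid-ranks, with average ranks for ties and
pairwise deletion of missing values (per-class cells can be empty for
cases with no spines of a class). p-values use the t approximation with
n − 2 degrees of freedom above n = 9 and exact permutation enumeration at
or below it. Multiplicity is controlled per region across all cells of the
grid with Storey q-values: pi0 is estimated by the smoother over
lambda = 0.05, ..., 0.95 when at least 20 p-values are available, falling
back to the fixed lambda = 0.5 estimate (floored at 1/m) and then to 1 for
short lists; with pi0 = 1 the q-values reduce exactly to
Benjamini–Hochberg, which is how the tests pin them. Cells are flagged at
FDR 10% and annotated "**" at the stringent 5% level, matching the usual
heatmap convention.

## Problem sizes and determinism

Every stochastic stage takes an explicit seed and is deterministic given
it. The test suite's replicate experiments use 100 default cohorts for
parameter recovery (head diameter ranked first in at least 80% of
BA37-like replicates; the pathology+sex+head-diameter model beats
pathology+sex in the majority; no such gain on beta_hd = 0 cohorts) and
200 all-null cohorts for the FDR check (flagged fraction at q < 0.1 held
near, in practice well under, the nominal 10%), with LASSO repeats at 25
per cohort. `scripts/acceptance.R` re-runs the whole pipeline at the seed
it is given and writes the headline numbers as JSON.

## Known limitations

* The generator's class-conditional distributions and effect sizes are
  invented (documented defaults, overridable); recovery results speak to
  estimator behaviour, not biology.
* Bootstrap MSE intervals undercover (above).
* lambda-min penalty selection over-selects under the null (above).
* The classifier's residual-stubby routing of boundary cases is a
  convention; flagged spines should be inspected when the rule order of a
  specific tracing package matters.
* No mixed-effects structure: neurons within a case are treated as
  exchangeable and aggregation to case level discards within-case
  correlation structure.
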