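---
title: "Region-specific brain-aging trajectories: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-specific brain-aging trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionbag)
```

## The model

`regionbag` estimates, separately for every brain region and imaging
modality, how far an individual's brain appears to have aged relative to
their chronological age. Three voxel-level features stand in for brain
structure and function: gray-matter intensity (GM) from T1-weighted MRI,
the per-voxel standard deviation of the resting-state fMRI time series
(SD) — a measure of BOLD-signal variability that declines with age — and
fractional anisotropy (FA) from diffusion imaging. Gray matter is
parcellated with the 90-region AAL atlas (GM and SD maps) and white matter
with the 48-tract JHU-ICBM label atlas (FA maps), giving 90 + 90 + 48 =
228 region models.

For one region, the model chain is:

**Key-voxel selection.** Not every voxel in a region tracks age. On a
random 70% subsample of the training controls the Pearson correlation of
each voxel with age is computed and the top 50% of voxels by |r| kept;
this inner step is repeated (nominally 1,000 times) and the iterations
intersected, the whole procedure run (nominally 100 times) under
independent seeded substreams, and the union of the consensus sets taken
as the region's key voxels. Ranking uses the *absolute* correlation by
default: the aging effects of interest are declines, i.e. negative
correlations, which signed ranking would discard; a signed mode is
available (`selection_config(signed = TRUE)`).

**Gaussian-process age prediction.** Key voxels are z-scored with
training-set statistics and mapped to age by GP regression with kernel
`k(x, x') = sf2 * x.x' + sn2 * I` (a linear kernel plus white noise; an
RBF kernel is available by configuration). With far more voxels than
subjects, a linear kernel is the standard choice for brain-age GPR and
makes the posterior mean a regularised linear readout of the features.
Hyperparameters maximise the log marginal likelihood (L-BFGS-B from a
fixed grid of starting values, so fits are deterministic). Fivefold
cross-validation — folds stratified by age quintile and seeded — yields an
out-of-fold prediction for every training subject before the model is
refit on the full training set.

**Bias correction.** Regularised age predictors overestimate young and
underestimate old subjects. The linear bias `raw = alpha*age + beta` is
fitted by OLS on the training out-of-fold predictions only (a population
independent of every evaluation set) and removed additively:

```
corrected = raw + (age - (alpha*age + beta))
BAG       = corrected - age = raw - (alpha*age + beta)
```

On the fitting population this restores unit slope and zero intercept of
corrected age on age exactly (an OLS identity the test suite asserts to
1e-8) and makes BAG orthogonal to age. The divisive alternative
`corrected = (raw - beta)/alpha` is kept behind
`pipeline_config(correction_form = "divisive")`. The additive form is the
default because the correction is defined to incorporate chronological age
directly; note its one systematic consequence: a true effective-age shift
of `delta` years is recovered as `slope_model * delta`, where
`slope_model` (the regression slope of raw prediction on age, typically
0.90–0.95 at the default noise level) reflects unavoidable model
shrinkage. The divisive form removes this attenuation at the cost of
dividing by an estimated slope.

**Group comparison.** Each patient group is compared with a control group
of the same size drawn without replacement from the independent healthy
test set, with per-sex counts matching the patient group's sex ratio
(rounded). BD-vs-control and MDD-vs-control are two separate two-group
ANCOVAs with independently matched controls, not a three-group model. Per
region, `bag ~ group + age + sex + mmse + education` is compared with the
covariate-only model; the group F statistic comes from the two residual
sums of squares (1 numerator degree of freedom), the effect size is
partial eta-squared `SS_group / (SS_group + SS_error)`, and the direction
is read from covariate-adjusted group means. Age stays a covariate even
though BAG is constructed orthogonal to age on the training set: in
patients and matched controls residual age dependence is possible and is
deliberately controlled. The FDR family is all regions within one
(comparison, modality) map — 90, 90, or 48 tests — because significance
counts are reported per map type; Benjamini–Yekutieli is the default (the
conservative choice, valid under arbitrary dependence between region
tests, which share subjects), Benjamini–Hochberg a flag. A region counts
as *accelerated* only when the adjusted p-value is below 0.05 **and** the
patient adjusted mean BAG exceeds the control mean. Partial correlations
of BAG with clinical scores (YMRS, HAM-D-21, HAM-A, MMSE, illness
duration) control for age and sex by residualisation, with one FDR family
over all tested (region, variable) pairs.

## The synthetic-cohort generator

Real clinical imaging cannot be shipped, so every stage is exercised on a
seeded generator whose defaults reproduce the target study design: 230
training controls with ages drawn uniformly over 20–84 (the uniform choice
maximises trajectory coverage; only the range is prescribed), 110 test
controls, 110 BD and 68 MDD participants, 50% female per group. Voxels
are either *informative* — `value = b0 + b1*effective_age + e` with
`b1 < 0` drawn from 0.015–0.035 units/year and `e ~ N(0, 0.5)` — or *pure
noise* around their baseline (`pure_noise_sd`, default 0.5, deliberately
independent of the informative-voxel noise so the noiseless-signal limit
retains genuine noise voxels rather than constants). FA slopes and noise
are scaled by 0.005 and values clipped to [0, 1] so tracts stay inside the
physical FA range. With 20 informative voxels per region these settings
give per-subject age uncertainty of about 4–5 years and cross-validated
MAEs of 3–4 years with r ≈ 0.97 — the regime of real region-wise brain-age
models.

Patient effects are modelled as an effective-age shift: in affected
regions a patient's voxels take the values of a healthy brain `delta`
years older. This makes the injected `delta` directly interpretable as
expected BAG (up to the shrinkage factor above) and parameter recovery a
well-posed test. Covariates (MMSE, education, clinical scores) are
generated independently of the voxel data, which keeps the ANCOVA null
calibration clean; clinical scores correlate with nothing by construction,
so passing correlation tests demonstrates calibration, not sensitivity.

What the generator does *not* emulate — spatial autocorrelation between
voxels, site/scanner effects, nonlinear aging trajectories, realistic
covariate–imaging dependence, diagnosis-specific covariate distributions —
bounds what green tests show about real data: they validate the
machinery (selection, fitting, correction, inference) under the model's
own assumptions, not robustness to their violation.

## Numerical choices

- **Correlation ranking.** Voxels with numerically zero variance in a
  subsample are flagged and excluded from ranking; the retained count is
  `ceiling(top_fraction * n_rankable)`. Exact ties at the cutoff resolve
  to the lower voxel index, so selections are deterministic.
- **Consensus.** "Intersection across iterations" is read literally as
  the strict intersection over all inner sets; if it is empty (possible in
  noisy, small regions) the threshold relaxes once to a 0.9 consensus with
  a warning, and a region empty even then is flagged unselectable.
- **Strict intersection under pure noise.** Because all iterations
  subsample one fixed cohort, per-voxel rankings are dependent across
  iterations: a noise voxel whose whole-sample |r| lands far above the
  rank cutoff by chance can survive every subsample. Under the default
  fixture (40 noise voxels, 230 training subjects) a strict 1000-fold
  intersection retains a survivor in roughly 1 trial in 10. An
  independence argument would predict survival probability
  `0.5^1000`; it does not apply, and the package documents the dependent
  behaviour rather than pretending otherwise.
- **GPR conditioning.** For the linear kernel the Gram matrix is
  eigendecomposed once, making each marginal-likelihood evaluation O(n);
  the noise variance is bounded below at `var(y) * 1e-8` so that
  noiseless (rank-deficient) feature sets still yield well-conditioned
  solves.
- **Seeds.** One master seed spawns fixed substreams per (modality,
  region, outer, inner) iteration, per fold assignment, and per
  matched-control draw, so any region is reproducible in isolation and
  whole runs replay bit-exactly from their manifest
  (`rerun_pipeline()`).
- **Degenerate inputs.** Constant ages, single-timepoint series,
  zero-variance features after standardisation, near-zero bias slopes
  (|alpha| < 1e-6), and rank-deficient ANCOVA designs raise typed errors;
  constant covariates are dropped from the ANCOVA rather than treated as
  collinear; missing clinical values stay missing and are removed
  listwise per analysis.

## Problem sizes used by the tests and the acceptance script

Resampling studies run at sizes chosen to characterise behaviour well on a
single CPU: the census run uses the full 228-region layout at 40 voxels
per region with 50 inner x 5 outer selection iterations (the nominal
1000 x 100 procedure is identical in structure and available through
`selection_config()`); parameter recovery uses 20 replicates of a
10-region gray-matter fixture with `delta = 5`; null calibration uses 200
replicates of a 3-region fixture with 40 training controls. The methods
are unchanged across scales — only iteration and replicate counts differ.

## Known limitations

- The GP uses a single kernel family per run; no composite or per-region
  kernel search is attempted.
- Matched controls are drawn once per comparison per run (seeded);
  sensitivity to control resampling can be probed by varying the run seed
  but is not averaged automatically.
- The ANCOVA is cross-sectional; no longitudinal, mixed-effects, or
  site-harmonisation modelling is in scope.
- 3-D rendering of results is out of scope; diagnostics are tabular and
  2-D (`autoplot()`).
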