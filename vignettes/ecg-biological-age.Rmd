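---
title: "Methods: ECG-derived biological age and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG-derived biological age and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic cohort generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## The problem

A 12-lead ECG analysed by an automated measurement system yields several
hundred numeric parameters per patient. Many track aging: conduction
intervals lengthen, axes rotate, wave amplitudes decline. A *biological age*
(BA) compresses an ECG parameter panel into a single age-scaled score; the
scientific question is whether that score discriminates mortality better
than chronological age (CA) itself, overall and within CA bands where CA has
little discriminating range left.

The package operates on a per-patient table: CA, sex, follow-up days, vital
status, death cause, optional exclusion flags and covariates, plus any
subset of a 438-parameter catalogue (6 not lead-specific parameters and 36
lead-specific ones measured in each of the 12 standard leads; column naming
`"<Parameter>__<Lead>"`). A companion list of 201 parameters (timing
coordinates, alternative QTc corrections, and similar derived duplicates) is
carried for accounting but never modelled.

## Cohort preparation

Patients are excluded for structural heart disease, CA outside [20, 90]
(bounds inclusive), indeterminate QRS axis (R axis > 180°), pacing, or
tachyarrhythmia, in that order; each removed patient is attributed to the
*first* matching criterion, so per-criterion counts always sum to the total
removed. The criteria are patient-level and independent of follow-up, so
exclusion commutes with follow-up truncation (a property the tests assert).

Follow-up is truncated at 3 years = 1095.75 days, using the same 365.25-day
year as the patient-year incidence denominator. A death recorded after the
cap lies outside the observation window of the binary-outcome design and is
relabelled alive — the ROC analysis is of end-of-window vital status, not of
time-to-event, so no censoring machinery is appropriate or used.

Missing values are tolerated only in the optional covariates (creatinine,
height, weight). A missing or non-numeric ECG cell is an error at read time:
the modelling stages are defined on complete cases, and silently dropping
rows would make the selection and calibration cohorts ambiguous.

## Two-step parameter selection

Both thresholds are applied to absolute correlations. The step-1 screen
keeps parameters with |r(x_j, CA)| ≥ θ₁ = 0.2 computed within each sex;
age-declining parameters (e.g. R-wave amplitudes) carry as much signal as
age-increasing ones, and their direction is preserved downstream through
regression slopes, so discarding negative correlations would be wrong.

Step 2 computes all pairwise correlations among step-1 survivors (within
sex). A pair with |r| ≥ θ₂ = 0.9 is a *strong correlation*. A parameter is
retained iff it belongs to no strong pair, or its step-1 |r with CA|
strictly exceeds that of every strong-pair partner. An exact tie is broken
toward the lexicographically first column name — deterministic and
recorded — rather than arbitrarily. The scan is over unordered pairs; the
X(X−1) ordered-pair count conventionally quoted for such scans is reported
alongside for reference (`ordered_pair_count()`).

This keep-iff-maximal rule guarantees the post-condition that no two
retained parameters are strongly correlated: in any strong pair at most one
member can dominate the other. The guarantee holds per sex.

**Combining the sexes.** Selection is per sex, but a single pooled model
needs one column list. The default is the *union* of the per-sex step-2
lists. The natural-looking alternative — the intersection — interacts badly
with strong collinearity: inside a block of near-duplicate parameters the
step-2 survivor is decided by sampling noise in the age correlations, so the
two sexes frequently keep *different* members of the same block and the
intersection loses the block entirely even though both sexes carry its
signal. The union preserves block coverage at the cost of occasionally
retaining two near-duplicates (one per sex) in the pooled fit, which the
estimators tolerate (it mildly re-weights that block). `sex_mode` /
`selected_parameters(mode=)` expose intersection and single-sex lists for
users who want them, and an explicit `columns` override exists because the
published analyses of this kind do not always document how their final panel
was reduced.

## Principal-component biological age

Inputs are standardized per column (mean 0, sd 1, denominator n − 1) with
the standardization stored for later application to new data — PCA is on the
correlation matrix, matching the standardized-inputs design. Unrotated
components with eigenvalue ≥ 1.0 (inclusive) are retained.

Eigenvector signs are mathematically arbitrary, but the weighted composite
is not sign-free, so each retained component is oriented to correlate
non-negatively with CA. Component weights are p_i = R²_i / Σ R²_k with R²_i
from the univariate regression of CA on component-i scores (sign-free, so
orientation does not affect the weights). The composite

pre-BA = Σ_i p_i Σ_j β_ij z_j

is centred on the training cohort by construction. Calibration uses
BA = pre-BA·sd(CA) + C̄A + (CA − C̄A)(1 − B), where B is the standardized
coefficient of the regression of pre-BA on CA, computed as the Pearson
correlation r(pre-BA, CA) — algebraically identical for standardized
regressions and numerically stable. Because both pre-BA and (CA − C̄A) are
centred, mean(BA) = mean(CA) on the training cohort; the tests assert this
to numerical tolerance. Note that pre-BA is not variance-normalised, so for
highly collinear panels BA can have larger spread than CA — wide BA ranges
are a property of the construction, not a bug.

## Klemera–Doubal biological age

Each parameter is regressed on CA by ordinary least squares: slope k_j,
intercept q_j, residual RMSE s_j and correlation r_j. The method is defined
against the unobservable true biological age; CA is its measurable
surrogate in these regressions. The RMSE uses the population convention
sqrt(SSE/n). Inside r_char, correlations enter as |r_j| so that
age-declining parameters contribute positive weight — their direction is
already encoded in k_j. A parameter with s_j = 0 or |r_j| = 1 (an exact
linear function of age) makes the estimator degenerate and is rejected with
an instruction to remove it.

BA_E is the precision-weighted least-squares inversion of the panel: it
minimises Σ_j [(x_j − q_j − k_j t)/s_j]² over t, which the tests verify
against an independent numeric minimiser. BA_EC adds CA as one more
pseudo-biomarker with variance s²_BA, so every BA_EC lies between BA_E and
CA, approaching BA_E as s²_BA → ∞ and CA as s²_BA → 0.

The s²_BA estimator is implemented in the canonical Klemera–Doubal form

s²_BA = Var_n(BA_E − CA) − (1 − r²_char)/r²_char · (CA_max − CA_min)²/(12 m),

with Var_n the divide-by-n variance. The subtracted term is the sampling
noise m biomarkers contribute to BA_E under a uniform age range; what
remains estimates the true dispersion of biological age around CA. (The
printed source formula for this quantity is typographically corrupted —
unbalanced brackets and mixed subscripts — so the package states and
documents the canonical form rather than guessing at the typography; the
structure of the printed form matches.) For small cohorts or weak panels
the correction can exceed the observed variance; the estimate is then
floored at 1e−8 with a warning, which keeps BA_EC defined (it collapses to
CA) instead of failing.

## AUC and DeLong inference

Outcomes are binary status at the end of truncated follow-up: all-cause
death, and cardiovascular death with non-cardiovascular deaths kept in the
control group (they are genuine non-events for the cardiovascular
endpoint). The AUC is the Mann–Whitney concordance probability with ties
counted ½, computed via midranks; per-event and per-control placement
values give the DeLong variance. Confidence intervals are normal on the AUC
scale, truncated to [0, 1]; per-predictor p-values test AUC = 0.5 with the
DeLong variance and are labelled as such. Paired comparisons between
predictors use the covariance of placement values; unpaired comparisons of
one predictor across disjoint CA categories sum the two independent
variances. All p-values are two-sided normal; a self-comparison with zero
variance returns p = 1 by convention. Strata with no events (typically the
youngest) are reported as not evaluable rather than silently dropped.
The implementation is cross-checked in the test suite against pROC, which
agrees exactly on AUCs, variances and z statistics (pROC's unpaired p uses
a t reference where this package follows the normal).

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical skeleton the analysis assumes,
with defaults chosen once as the package's study conditions:

- **CA**: truncated normal on [20, 90] whose *realized* mean and SD equal
  the configured 55.5 and 15.0 years (the parent parameters are solved by
  moment matching; plain truncation of N(55.5, 15²) would shrink the SD to
  about 14). Sex is male with probability 0.537.
- **Latent biological age**: true BA = CA + N(0, latent_noise_sd²),
  latent_noise_sd = 5 years — the scale of biological-age dispersion usually
  reported for biomarker BAs.
- **Parameter blocks**: 10 blocks of 5 parameters (50 of the 438 catalogue
  columns). Each block has a driver correlating age_loading = 0.7 with the
  latent age; members correlate sqrt(0.95) with their driver, so
  within-block pairwise correlations are 0.95 in expectation — the strong
  collinearity regime step 2 is designed to prune, while cross-block
  correlations (≈ 0.47) stay below the threshold. Fixed per-parameter
  affine transforms with alternating sign map to native units, so roughly
  half the parameters decline with age.
- **Mortality**: exponential hazard, baseline 0.5 per 100 patient-years,
  log-hazard increasing by accel_log_hazard per year of (true BA − CA);
  uniform follow-up on (0, 1095.75]; death causes cardiovascular with
  probability 23/55. The baseline is deliberately *flat in CA* so that
  discrimination isolates the biological-aging component; consequently
  accel_log_hazard = 0.25/year, set by a design-time power calculation so
  that the signal is detectable (AUC confidence interval excluding 0.5) in
  cohorts of ~10⁴ patients over a three-year window. A literature-typical
  per-year hazard ratio of ~1.05 would need cohorts far beyond desk scale
  to show anything under an age-flat baseline.
- **Reproducibility**: every logical stage draws from its own stream seeded
  from the master seed, so identical seeds give identical cohorts.

What the generator does **not** emulate: electrophysiological ECG
morphology or realistic units; age-dependent baseline mortality; informative
censoring; sex differences in parameter–age structure; non-linear
parameter–age trends; measurement batch effects. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes — linear
age-loaded collinear blocks with sparse exponential mortality — not that it
would perform equally on registry data, where the selection counts, r_char,
s²_BA and AUCs can differ substantially.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline on simulated
cohorts of 5,000 patients (10,000 for the discrimination-at-scale check),
verify BA_E against a numeric weighted-least-squares oracle on 100 random
panels of up to 5 biomarkers, and calibrate the paired DeLong test on 2,000
replicates of 200 patients — sizes at which Monte-Carlo error is small
relative to the tolerances asserted while a full run stays in seconds.
Other numerics: the eigenvalue cutoff is applied with a 1e−12 slack so an
exactly-1.0 eigenvalue (single-column panel) is retained under floating
point; correlations are computed with the n − 1 convention everywhere
except Eq.-style population variance inside s²_BA; standardization errors
name the offending constant column; and all serialisation
(`write_pipeline()`, `write_cohort()`) keeps full double precision so
round-trips are bit-identical.

## Known limitations

- The binary-outcome ROC design ignores censoring within the window; with
  uniform entry this biases all predictors alike, but time-dependent ROC
  or Cox modelling is out of scope by design.
- The published analyses this pipeline mirrors reduced their selected panel
  further (to 26 parameters) by an undocumented step; the package
  deliberately exposes the final panel as configuration instead of
  guessing.
- BA_E's wide range on weakly informative panels (and s²_BA flooring) are
  inherent to the Klemera–Doubal construction at modest r_char; the package
  reports r_char and s²_BA so users can judge panel adequacy.
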