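---
title: "Linking white-matter microstructure to sleep-wake disturbance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking white-matter microstructure to sleep-wake disturbance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepwm)
```

## The analysis problem

Clinical high-risk cohorts for psychosis show both subtle white-matter
alterations — usually summarized as lower fractional anisotropy (FA) — and
elevated sleep-wake disturbance. `sleepwm` implements the full statistical
chain needed to study their association in a two-group (patient/control)
design in which each subject contributes:

* a 48-region FA profile (JHU ICBM-DTI-81 tract labels, mean skeleton FA per
  region);
* seven ordinal Karolinska Sleep Questionnaire items per recall period;
* one night of wrist actigraphy (1-min epoch activity counts) plus a sleep
  diary giving bed and rise times;
* nuisance covariates: age, sex, absolute and relative head motion in the
  scanner, and optional clinical covariates (depressive-symptom total, a
  composite symptom score, medication and substance-use indicators).

The package deliberately starts *after* image processing: it consumes a
per-subject ROI FA table and never touches voxel data.

## Subjective sleep indices

The seven questionnaire items, each scored 1 = never to 5 = always, split
into two indices:

* **DSI** (disturbed sleep) = items (a) difficulty falling asleep +
  (b) disturbed/restless sleep + (c) repeated awakenings + (d) premature
  awakening; range 4-20.
* **AWI** (disturbed awakening) = items (e) difficulty waking +
  (f) non-refreshing sleep + (g) exhaustion at awakening; range 3-15.

A missing item makes the whole index missing and the subject is excluded
listwise from any analysis using that index; the pipeline attributes every
exclusion to a named rule so subject counts always reconcile.

## Actigraphy scoring and summary measures

The vendor scoring algorithm behind commercial actigraphy reports is not
published in a reusable form, so the package uses the published Cole-Kripke
1-min weighted-sum classifier as its default and only scorer: epoch $t$ is
scored sleep when

$$0.001\,(106\,A_{t-4} + 54\,A_{t-3} + 58\,A_{t-2} + 76\,A_{t-1}
  + 230\,A_{t} + 74\,A_{t+1} + 67\,A_{t+2}) < 1,$$

with counts outside the recording taken as zero. Epochs are half-open
minutes $[t, t+60\,\mathrm{s})$; an epoch is in bed when its start lies in
`[bed_time, rise_time)`, with the diary taken as authoritative for the rest
interval. From the in-bed labels:

* `tst` — sleep minutes; `waso` — wake minutes after the first sleep epoch;
* `se` $= 100\,\mathrm{TST}/\mathrm{TIB}$;
* `mi` (movement index) $= 100 \times$ wake minutes / time in bed
  *in minutes*. Printed definitions of this index sometimes divide by time
  in bed in hours, which does not yield a bounded percentage; the per-minute
  denominator is used here and keeps `mi` in $[0, 100]$, commensurate with
  the fragmentation index;
* `fi` (fragmentation index) $= 100 \times$ (number of sleep bouts of length
  exactly one minute) / (number of sleep bouts);
* `sfi` $=$ `mi` $+$ `fi`.

Whenever at least one epoch is scored sleep, the identity
`latency + tst + waso = time_in_bed` holds epoch-exactly; all-wake nights are
flagged (`no_sleep`) rather than silently summarized, and flagged subjects
are excluded from the analyses.

## FA aggregation

`global_mean_fa()` is the weighted average of the 48 ROI values. No
universally agreed weighting exists for skeletonized atlas summaries, so the
default is equal weights, with per-ROI skeleton voxel counts accepted as an
optional weight vector. `callosal_fa()` is the arithmetic mean of the genu,
body and splenium values. Input tables are validated against the canonical
48-label list (exact match after whitespace normalization) so that silently
misnamed columns cannot enter an analysis.

## Univariate inference

* **Group tests** use the nested-model F: residual sums of squares of
  `y ~ covariates` versus `y ~ group + covariates`, 1 numerator df, exact F
  reference. With a single two-level factor plus continuous covariates this
  is unambiguous (no Type II/III distinction arises).
* **Partial correlations** are Pearson correlations of the OLS residuals of
  both variables on an intercept plus covariates; the two-tailed p-value uses
  the t transform with $n - k - 2$ df. Confidence intervals are subject-level
  nonparametric percentile bootstraps (default $B = 1000$), re-residualizing
  each resample; degenerate resamples are redrawn with a cap of $10B$
  attempts.
* **FDR** control is Benjamini-Hochberg step-up via `stats::p.adjust`. In
  the pipeline, the correction family is the 2 FA summaries $\times$ 6 sleep
  measures within each cohort analysis (pooled, patients, controls), i.e.
  12 p-values per family — the same family structure in which such
  correlation grids are usually reported.
* **Mediation** is simple OLS path analysis ($a$ from `m ~ x + cov`; $b, c'$
  from `y ~ x + m + cov`; $c$ from `y ~ x + cov`) with a percentile bootstrap
  for the indirect effect $ab$. For these linear models $c = c' + ab$ holds
  exactly, which the tests assert.

Sex is coded 0/1 throughout and treated as any other numeric covariate.

## Partial least squares correlation

Both blocks are first residualized column-wise on an intercept plus the
covariates and scaled to unit sample variance (divisor $n-1$); partialling
is done *before* the decomposition, the standard behavioural-PLS treatment
of "co-varied for" nuisance variables. The cross-block matrix

$$R = X_r^\top Y_r / (n - 1)$$

then holds correlations, so singular values are scale-free and the
covariance-explained fractions $\sigma_k^2 / \sum_j \sigma_j^2$ are
interpretable as percentages. The SVD $R = V \Sigma U^\top$ yields paired
saliences; the sign indeterminacy is fixed deterministically by making the
largest-magnitude element of each Y-salience positive. The identity
$\sum_k \sigma_k^2 = \lVert R \rVert_F^2$ is asserted on every fit.

**Permutation test.** Rows of $Y_r$ are shuffled and the decomposition refit
without any rotation. The omnibus statistic is the inertia
$\sum_k \sigma_k$; per-LV p-values compare the $k$-th singular value of each
permuted fit against the observed $k$-th value (non-rotated sampling
distribution). Both use the add-one estimator
$p = (1 + \#\{\text{exceedances}\})/(1 + n_{\mathrm{perm}})$, which cannot
return zero.

**Bootstrap.** Subjects are resampled jointly with replacement and each
resample re-standardized and refit. Because the SVD axes of a resample may
be arbitrarily rotated or reflected relative to the point estimate, each
bootstrap solution is aligned by orthogonal Procrustes rotation — solved on
the Y-saliences and applied to both blocks — before percentile 2.5/97.5
intervals are formed per salience element. An element is *reliable* when its
interval does not cross zero. Procrustes alignment lives only in the
bootstrap; the permutation branch is deliberately non-rotated.

**Reporting rule.** An LV is reportable when it explains more than 5% of the
cross-block covariance ($\sigma_k^2/\sum \sigma_j^2 > 0.05$) *and* its
permutation p-value is below 0.05. The squared-singular-value scale is used
because those fractions sum to one.

**Group analyses.** `groupwise_plsc()` runs an independent PLS-C per group,
residualizing within group. How a two-group "interaction" decomposition
should be constructed is not standardized; the package's documented choice
for the group contrast is the inertia of $R_{\text{group1}} -
R_{\text{group2}}$ with group labels permuted (sizes fixed) and within-group
residualization repeated per permutation. Under exchangeability this gives a
valid permutation p-value for "does the covariance pattern differ by
group?". Y is standardized within each analysis sample (within group for
within-group analyses, pooled for the pooled analysis).

Defaults are `n_perm = n_boot = 10000`, overridable upward to 100000 for
final reports; the estimator is unchanged by the count, only its Monte-Carlo
resolution. The test-suite runs use 200-2000 to keep the suite fast.

## The synthetic cohort generator

Because no subject-level data are distributable, the generator is a
first-class module producing cohorts with the statistical structure the
analysis assumes, for calibration and power checks:

* **Covariates** are drawn near the magnitudes typical of such cohorts
  (age $\approx 23.6 \pm 3.9$ years, about 58% male patients vs 40% male
  controls, absolute motion $\approx 1.26 \pm 0.35$ mm, relative motion
  $\approx 0.18 \pm 0.08$ mm).
* **FA**: per-ROI baselines are fixed constants in $(0.4, 0.8)$ (callosal
  segments near 0.74-0.755); a patient deficit (default 0.013 FA units,
  matching a global FA gap of $0.599$ vs $0.612$), small covariate slopes,
  the planted latent term, a per-subject global offset
  ($N(0, 0.012)$, shared by all ROIs, reproducing the between-subject
  spread of global mean FA) and $N(0, 0.01)$ per-ROI noise are added, with
  reject-and-resample (never clipping) to keep every value in $(0, 1)$.
* **Latent coupling**: a zero-mean score $z \sim N(0, 1)$ per subject feeds
  a sparse X-loading vector (default $\pm 0.015$ FA units/SD on six ventral
  ROIs: fornix up; corticospinal tracts, left cerebral peduncle, left medial
  lemniscus, left hippocampal cingulum down) and the six sleep measures.
* **Questionnaire**: a latent-Gaussian (probit-style) ordinal model with
  four fixed cut-points `(-0.7, 0.3, 1.3, 2.3)` shared across items; item
  slope = (DSI loading)/4 for items a-d, (AWI loading)/3 for e-g, so the
  expected index shift per latent SD approximates the loading (the local
  slope of the expected item score is about 1 near the scale center).
  Patients receive an additive shift (`latent_group_shift`, default 1 SD) on
  this channel only, reproducing a large subjective group difference
  (DSI roughly 12 vs 8.5) without separating the actigraphy measures —
  the configuration observed in such cohorts.
* **Actigraphy**: a two-state (sleep/wake) first-order Markov bout process
  per in-bed minute — geometric bout durations are the tractable special
  case of the semi-Markov family — modulating Poisson counts (wake
  $\lambda = 60$, sleep $\lambda = \mathrm{logit}^{-1}(w) \le 1$, daytime
  $\lambda = 250$). The latent enters as wake propensity
  $w = z \times (\text{WASO loading})/20$, i.e. a 20-min-per-SD loading maps
  to one unit of $w$; it raises the sleep-to-wake hazard, wake persistence,
  the chance of starting the night awake, and in-sleep movement. TST/SE/SFI
  couplings are emergent from the same bout process rather than injected
  separately. At $w = 0$ the scored summaries average TST $\approx 410$ min,
  WASO $\approx 54$ min, SE $\approx 86$%, SFI $\approx 17$ — the magnitudes
  reported for one-night wrist actigraphy in young clinical samples.
* **Reproducibility**: each subject has an independent random stream seeded
  from the master seed, so regeneration is bit-for-bit identical and
  independent of generation order.

Setting both loading vectors to zero yields a null cohort in which FA and
sleep share nothing beyond covariates; the permutation calibration tests run
on exactly this case.

**What the generator does not emulate:** raw accelerometry (counts are
generated at the epoch level), multi-night wear, daytime napping,
recall-period biases beyond extra night-to-night noise, item-specific
threshold differences, heavy-tailed motion artifacts, and any spatial
correlation structure among ROI noise terms. Passing tests on synthetic
cohorts therefore demonstrate statistical correctness of the machinery and
recoverability of planted effects — not that real cohorts satisfy the
generative assumptions.

## Numerical choices and degenerate inputs

* Zero residual variance after covariate adjustment is an error naming the
  offending column in user-facing paths; in permutation/bootstrap resampling
  branches, collapsed columns are zeroed (permutation) or the resample is
  redrawn with a capped attempt budget (bootstrap), so inference never
  silently divides by zero.
* All-zero cross-block matrices give all-zero singular values and undefined
  covariance-explained fractions (`NA`), not an error, in `fit_plsc()`;
  `covariance_explained()` itself rejects an all-zero vector.
* Sign ties in the salience convention resolve to the first
  largest-magnitude element (`which.max`), making results platform-stable.
* p-value estimators use the add-one correction throughout.
* The accounting identity (latency + TST + WASO = time in bed) is computed
  in integer epochs; diary durations are derived from raw seconds, never
  from unit-converted `difftime`, to avoid floating-point minute loss.

## Problem sizes used by the test-suite

The suite checks calibration and recovery at sizes chosen to make
Monte-Carlo error negligible while keeping the default run a few minutes:
permutation calibration on 500 null datasets ($n = 60$, $10 \times 4$
blocks, 1000 permutations; the exact binomial 95% band for a 0.05-level
test over 500 replicates is $[0.033, 0.071]$); salience recovery on 50
replicates at $n = 200$ with 2000 bootstraps (planted loadings: 8 of 48 X
variables and 3 of 6 Y variables active, noise SD 0.5); oracle agreement for
the SVD on 100 random $30 \times 4 / 30 \times 3$ instances at $10^{-10}$;
and brute-force oracle agreement for the scalar statistics at $10^{-12}$.

## Known limitations

* Cole-Kripke was calibrated for a particular device generation; applied to
  other devices' counts its absolute TST/WASO have device-specific bias.
  Within this package it is a fixed, documented, deterministic rule.
* The group-contrast PLS-C mechanism is one defensible construction among
  several; its p-value should be read as evidence about the difference of
  cross-correlation structures under that statistic.
* One-night actigraphy is inherently noisy at the subject level; the
  pipeline treats it as a supporting measure alongside the four-week
  questionnaire indices, mirroring how such data are used in practice.
* The bootstrap re-standardizes resampled residuals but does not refit the
  covariate regression within each resample; with the modest covariate sets
  intended here the difference is negligible relative to resampling noise.
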