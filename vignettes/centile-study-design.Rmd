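---
title: "Designing growth reference centile studies with centdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing growth reference centile studies with centdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centdesign)
```

## The model

`centdesign` works with the BCCG distribution (Box-Cox Cole–Green), the
distributional form of the LMS method that underlies most modern growth
references. A positive measurement $y$ at age $t$ is described by three
age-varying parameters: the median $\mu(t)$, the generalised coefficient of
variation $\sigma(t)$ (the generalised SD is $\mu\sigma$), and the Box-Cox
skewness power $\nu(t)$. The defining assumption is that the Box-Cox
transformed measurement is standard normal, so centiles and z-scores
interconvert in closed form:

$$C_{100\alpha}(t) = \mu(t)\,\bigl(1 + \nu\sigma z_\alpha\bigr)^{1/\nu},
\qquad
z = \frac{(y/\mu)^\nu - 1}{\nu\sigma},$$

with the $\nu = 0$ limits $\mu e^{\sigma z}$ and $\log(y/\mu)/\sigma$. The
density carries the Jacobian $(y/\mu)^\nu/(\sigma y)$ and ignores the
truncation of $y$ to positive values, which is negligible for the
$\sigma|\nu|$ values seen in anthropometry and is the standard LMS
convention. Kurtosis-extended families (BCT, BCPE) are deliberately out of
scope: their extra parameter only affects centiles beyond roughly the 1st
and 99th, which most charts do not display.

Working on the z-score scale is what makes a *generic* design theory
possible: for a single age group of $n$ normal observations the centile
standard error in z-score units is $SE_z = \sqrt{(1+z_\alpha^2/2)/n}$,
independent of the measurement and its units (`se_z_normal()`,
`n_from_se()`). Note that this formula describes the parametric estimate
$\hat\mu + z\hat\sigma$; the raw sample quantile is noticeably less
precise, which is one reason reference centiles are model-based.

## Fitting the moment curves

`fit_bccg()` estimates $\mu(t), \sigma(t), \nu(t)$ from a cross-sectional
`(age, y)` dataset by penalized maximum likelihood. The numerical scheme
is the package's own:

* **Bases.** Each smooth curve is a cubic B-spline on 20 equally spaced
  segments (23 basis functions) with a second-order difference penalty
  (P-splines), so the penalty null space is a straight line and the edf of
  a smooth term ranges from 2 to 23. Curve classes `linear` and `constant`
  are available per moment; degenerate inputs (all ages equal) fall back to
  constants automatically.
* **Links.** Identity for $\mu$ (with a positivity check each step), log
  for $\sigma$, identity for $\nu$, with $\nu$ clamped to $[-4, 4]$.
* **Backfitting.** The three moments are updated cyclically by one
  penalized IRLS step each, using the Cole–Green expected information
  weights ($W_\mu = (1+2\nu^2\sigma^2)/(\mu\sigma)^2$, $W_{\log\sigma}=2$,
  $W_\nu = 7\sigma^2/4$). Every coefficient update is step-halved until the
  penalized log-likelihood does not decrease, so the iteration ascends;
  convergence is declared when the penalized deviance changes by less than
  a relative `tol` (default 1e-6, cap 50 cycles), and non-convergence is an
  error rather than a silent result.
* **Smoothing parameters.** Updated once per cycle by a local
  maximum-likelihood (Schall-type) step
  $\lambda \leftarrow \hat\sigma^2_\varepsilon/\hat\tau^2$, clamped to
  $[10^{-4}, 10^7]$ and frozen after 15 cycles so the deviance criterion
  can settle.
* **Age transform for the median.** $\mu$ is fitted against $t^\xi$,
  $\xi \in (0,1]$, which absorbs the steep infancy rise; $\sigma$ and
  $\nu$ are fitted against untransformed age, where transformation helps
  little. `select_xi()` profiles $\xi$ on a grid with the median edf held
  constant. The profiling edf is the smaller of the ML edf at $\xi = 1$
  and 8: at a generous edf any scale fits equally well and the profile is
  flat, while at a modest edf the wrong scale visibly underfits; the cap
  makes the criterion discriminating without biasing the final fit, which
  is re-run with ML smoothing at the chosen $\xi$.
* **Skewness curve class.** With `nu_class = "auto"` the model is fitted
  with constant, linear and smooth $\nu$ and the GAIC(3) minimiser kept,
  ties broken toward fewer edf. GAIC(3) rather than BIC because reference
  datasets are large and BIC over-penalises; `information_criteria()`
  returns both.
* **Monotone-median constraints** are not implemented: the simulation
  pipeline never needs them, and none of the fitted quantities used by the
  design layer depend on enforcing monotonicity.

The median curve is linear in its spline coefficients, so its pointwise SE
comes exactly from the penalized-fit coefficient covariance
(`mu_se_z_curve()`, divided by $\hat\mu\hat\sigma$ to give $SE_z$). In the
single-age-group limit this reproduces $1/\sqrt n$, which the test suite
checks.

## The synthetic base models

`growth_fixture()` supplies four deterministic moment-curve sets on
[0, 20] years — weight, height, BMI, head circumference — built as
shape-preserving monotone cubics through small anchor tables of realistic
boys' values: medians steep in infancy then decelerating, a mild pubertal
inflection for height and weight, the infancy peak and adiposity rebound
for BMI, and slowly varying CV and skewness curves. Their role is to give
the simulation machinery base models with the right *qualitative* geometry;
they are synthetic, and no numerical agreement with any published reference
is claimed. Each fixture's median straightens (minimum integrated squared
curvature against rescaled $t^\lambda$) near the age power a practitioner
would use for that measurement — about 0.5 for height, 0.7 for weight,
0.3 for BMI and head circumference — which the tests assert as brackets.

What the fixtures do **not** emulate: measurement error and digit
preference, sampling bias, secular trends, kurtosis, and the adult
plateau beyond age 20. Tests that pass on fixture data therefore validate
the *machinery* (fitting, bootstrap, design logic), not the behaviour of
any particular real dataset.

Datasets are simulated by inverse-transform sampling of ages — uniform
deviates between $t_{\min}^\lambda$ and $t_{\max}^\lambda$ raised to
$1/\lambda$ — followed by a uniform proportion per subject converted
through the BCCG centile transform (`simulate_dataset()`). Grouped designs
draw exact per-group counts uniform within groups (`nagegp()`,
`grouped_ages()`); group counts are integerized by largest-remainder
rounding, which conserves the total exactly and is the natural choice where
no convention is published. Edge multipliers (≥ 1, default 1) inflate the
first and last groups before renormalization; this is a documented
convention for handling edge effects, not a published formula.

## Bootstrap SE_z curves

`bootstrap_se_curves()` resamples rows with replacement, refits, evaluates
each requested centile on an age grid, converts those centiles to z-scores
*through the original fit's moments*, and takes the SD across replicates.
Choices worth knowing:

* Resampling is unstratified by default (stratified-by-age-group is an
  option); B defaults to 500, and scaled-down runs use 100.
* Replicate refits hold the smoothing parameters, $\xi$ and curve classes
  fixed at the base fit's values and warm-start from its coefficients.
  This is cheaper and more stable than re-selecting per replicate, at the
  price of not propagating smoothing-selection variability; the
  single-age-group limit checks show the resulting SE_z is calibrated to
  within the bootstrap's own noise.
* Non-converged replicates are dropped and counted; more than 10% failures
  is an error.

Curves are summarised as linear trends of $\log SE_z$ on age over 2–18
years (edge effects excluded), age centred at 10 (`sez_trend()`).

## The design layer

`design_model()` holds the meta-regression of $\log SE_z$ on age,
$\log(1+z^2/2)$ and $\lambda$ with the two age interactions. The packaged
default coefficients (−3.088, 0.537, −0.283, 0.0231, 0.0205, −0.0604;
reference n = 6878; scaling exponent 1.85) are published values shipped as
immutable named defaults; `fit_design_model()` re-estimates all six by OLS
from user-supplied curves and returns a *new* model object, never mutating
the defaults. From the model:

* `optimal_lambda()` solves the flatness condition
  $\lambda^* = (b_{age} + b_{age:z}\log(1+z^2/2))/(-b_{age:\lambda})$,
  erroring outside (0, 1] (design infeasible).
* `predict_se_z()` evaluates the first three terms and rescales to other
  sample sizes by $(n_{ref}/n)^{1/1.85}$.
* `required_n()` inverts the scaling law and rounds **up** (conservative).
* `centile_ci()` uses the multiplier 2 exactly (not 1.96), following the
  convention of the source framework; intervals for centiles above the
  median are the mirror images of those below.

One numerical convention deserves a note. The scaling law is estimated
from runs at $n/4$, $n$ and $4n$: the per-quadrupling SE_z ratio. A fixed
effective bandwidth would give exactly 2; adaptive smoothing gives a little
less, about 1.85, because larger samples support more wiggle. Calling that
number the *exponent* of $n \propto SE_z^{-1.85}$, as the design formulas
do, is not algebraically the same reading (a multiplier $m$ per factor 4
corresponds to $n \propto SE_z^{-\log 4/\log m}$, about $-2.25$ for
$m = 1.85$). The package follows the design-formula convention everywhere
numbers are produced (`predict_se_z()`, `required_n()`), and the test suite
checks the *measured* quantity — the per-quadrupling multiplier from
scaled-down reruns — against the 1.7–2.1 band.

## The flatten-λ loop

`flatten_lambda()` re-derives the optimal composition by simulation, the
loop the calculators summarise: simulate at $\lambda$ → fit → SE_z curve
(bootstrap; or the analytic median band when z = 0) → 2–18 y trend slope →
adjust $\lambda$ until the slope vanishes. Because a single slope
measurement is noisy (bootstrap plus simulation noise of order a few
thousandths per year, against a slope-tolerance default of 0.005), the
root is not taken from any single evaluation: the slope is close to linear
in $\lambda$ (it is the meta-regression's age:λ structure), so the loop
fits a least-squares line through *all* evaluations, proposes the next
$\lambda$ at its root, and returns the final line root. A `reps` argument
averages the slope over replicate datasets per evaluation. Evaluations are
capped (default 8) and the default inner bootstrap is B = 100 — scaled
down relative to production-quality B = 500 — with n = 6878 per dataset.

The package's worked fixture for this loop is height: its median
straightens at ξ ≈ 0.5 and its flattening powers land nearest the
published design optima. Run at the test suite's sizes (n = 6878, B = 100,
3 reps), the loop puts the median optimum near λ ≈ 0.29 and the
2nd-centile optimum near λ ≈ 0.63 — the same ordering and roughly the same
spacing as the meta-regression's 0.38 and 0.76, with the absolute level a
little lower. The shift is expected: the flattening power depends on the
base model's geometry and the smoother's borrowing profile, and the
published values pool three real measurements. The tests assert the
brackets [0.25, 0.50] and [0.60, 0.90] and the cross-route consistency of
the λ difference, not equality with the pooled values.

## Problem sizes and runtime

The package's own test runs use: n = 7000 for fitter-recovery checks,
n = 1000 with B = 400 for the single-age bootstrap limit, B = 60–100 and
n = 3000–6878 for pipeline reruns, and three sample sizes (1720, 6878,
27512) × 3 replicates for the scaling check. These sizes give Monte-Carlo
error comfortably inside the asserted tolerances while keeping a full run
in a few minutes; production use of `flatten_lambda()` or
`bootstrap_se_curves()` would raise B to 500.

## Known limitations

* Cross-sectional designs only: repeated-measures (cohort) data change
  both precision and bias in ways that need their own treatment, and are
  excluded.
* The design coefficients are estimated for ages 0–20/21; shorter age
  ranges need refitting (`fit_design_model()`) — precision does not simply
  scale with the range, and edge effects loom larger.
* BCCG only (no kurtosis); no monotone-median constraint; no worm-plot
  diagnostics.
* The fitter's smoothing-parameter path (local ML with a freeze) is one
  of several defensible schemes; edf values from other software will
  differ in detail even on identical data.
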