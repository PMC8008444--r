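# centdesign

Design tools for cross-sectional growth reference centile studies:
how many children to measure, and at what ages.

## The problem

Growth reference charts (weight, height, BMI, head circumference against
age) are built by fitting smooth centile curves to a cross-sectional sample.
Study teams planning such a reference face two design questions that
standard sample-size formulas do not answer:

* **Sample size** — the classical single-age-group result says the
  100α'th centile of `n` normally distributed measurements has standard
  error, in z-score units,

      SE_z = sqrt((1 + z_α²/2) / n),

  independent of the measurement and its scale. But centile curves are
  *smoothed* across age, which "borrows strength" from neighbouring ages and
  makes the effective age-specific sample size two to three times larger —
  so the naive formula materially over-states the required n.

* **Sample composition** — growth is fastest in infancy, so infants must be
  over-sampled. How much? `centdesign` parameterizes the age distribution
  as *uniform on the age^λ scale*: λ = 1 gives uniform ages, smaller λ
  over-samples infancy more.

The package implements the full simulation framework that answers both
questions for the LMS (BCCG) centile model: the distribution math, the
penalized-spline fitter, the age^λ simulator, bootstrap standard-error
curves on the z-score scale, and closed-form design calculators built on a
meta-regression of those curves,

    log SE_z = b₀ + b_z·log(1+z²/2) + b_λ·λ
             + (b_age + b_age:z·log(1+z²/2) + b_age:λ·λ)(age − 10),

with the packaged coefficients (−3.088, 0.537, −0.283, 0.0231, 0.0205,
−0.0604), reference size n = 6878, and the sample-size scaling law
n ∝ SE_z^−1.85. The optimal λ for a design centile z solves the *flatness
condition* (the three age terms cancel, so precision is constant across
age):

    λ* = (b_age + b_age:z·log(1+z²/2)) / (−b_age:λ)

giving λ* = 0.38 for the median rising to 0.90 for the 0.4th/99.6th
centiles.

## Worked example

Design a reference study around the 2nd centile (z = −2), the usual choice
because the outer centiles are the least precise that charts still show:

```r
library(centdesign)
dm  <- design_model()
lam <- optimal_lambda(dm, z = -2)
se  <- predict_se_z(dm, z = -2, lambda = lam, n = 7200)
ci  <- centile_ci(-2, se)
```

which prints

    optimal lambda: 0.76
    SE_z at n = 7200: 0.065
    95% CI for the 2nd centile: (1.7, 3.1)

So with 7200 children aged 0–20 sampled uniformly on age^0.76, the 2nd
centile is estimated to ±2 × 0.065 z-scores, i.e. the curve drawn as the
"2nd centile" is, with 95% confidence, somewhere between the true 1.7th and
3.1st centile — at every age, because λ was chosen to flatten the error
curve. Inverting the scaling law for a target precision, and allocating a
survey's subjects to one-year age groups:

```r
required_n(dm, z = 2, target_se = 0.06)
#> 8301
plan <- nagegp(sampling_scheme(lam, 0, 20, n = 10000), breaks = 0:20)
```

The allocation falls from 1041 infants in the first year to 380 in the
last (ages 19–20).

The simulation machinery behind the calculators is exported too:
`growth_fixture()` provides synthetic boys' anthropometry base models,
`simulate_dataset()` draws measurements under an age^λ scheme,
`fit_bccg()` fits the BCCG moment curves by penalized maximum likelihood,
`bootstrap_se_curves()` estimates SE_z curves for any centile, and
`flatten_lambda()` re-derives the optimal λ by simulation instead of from
the packaged coefficients. A command-line wrapper (`inst/exec/centdesign`,
subcommands `fixture`, `simulate`, `fit`, `se-curve`, `allocate`, `design`,
`flatten`) drives the same functions from the shell.

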