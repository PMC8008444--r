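# shared fixtures, built once per test run and cached
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# n = 7000 height-like dataset and its fit, reused by several test files
height_fit <- function() {
  cached("height_fit", {
    set.seed(42)
    fx <- growth_fixture("height")
    d <- simulate_dataset(fx, sampling_scheme(0.5, 0, 20, n = 7000))
    list(model = fx, data = d,
         fit = fit_bccg(d, fit_config(xi = 0.5, nu_class = "constant")))
  })
}

# single-age-group constant-parameter data, fit and B = 400 bootstrap
single_age_boot <- function() {
  cached("single_age_boot", {
    set.seed(43)
    d <- data.frame(age = rep(8, 1000), y = rbccg(rep(130, 1000), 0.05, 1))
    fit <- fit_bccg(d)
    curve <- bootstrap_se_curves(fit, z = c(-2, -1.33, 0, 1.33, 2), B = 400,
                                 seed = 44)
    list(data = d, fit = fit, curve = curve)
  })
}

expect_rel <- function(value, target, tol) {
  expect_true(abs(value / target - 1) < tol,
              label = sprintf("%g within %g%% of %g", value, 100 * tol,
                              target))
}
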