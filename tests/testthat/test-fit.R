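test_that("constant-parameter data are recovered by constant curve classes", {
  set.seed(21)
  d <- data.frame(age = stats::runif(5000, 0, 10),
                  y = rbccg(rep(50, 5000), 0.1, 1))
  fit <- fit_bccg(d, fit_config(mu_class = "constant",
                                sigma_class = "constant",
                                nu_class = "constant"))
  m <- predict_moments(fit, 5)
  expect_equal(m$mu, 50, tolerance = 0.5 / 50)
  expect_equal(m$sigma, 0.1, tolerance = 0.005 / 0.1)
  expect_lt(abs(m$nu - 1), 0.5)
  expect_equal(fit$edf, c(mu = 1, sigma = 1, nu = 1))
})

test_that("input validation catches unusable datasets", {
  expect_error(fit_bccg(data.frame(age = 1:10, y = 1:10)), "50")
  expect_error(fit_bccg(data.frame(age = stats::runif(60), y = rep(-1, 60))),
               "positive")
  expect_error(fit_config(xi = 1.5), "xi")
  expect_error(fit_config(n_knots = 2), "n_knots")
})

test_that("fitted centile curves recover a smooth truth", {
  hf <- height_fit()
  fit <- hf$fit
  g <- seq(2, 18, by = 0.1)
  truth <- eval_moments(hf$model, g)
  pm <- predict_moments(fit, g)
  dz <- z_from_measurement(truth$mu, pm$mu, pm$sigma, pm$nu)
  expect_lt(stats::median(abs(dz)), 0.05)
  # near the edges the tolerance is wider
  ge <- c(seq(0.1, 2, 0.1), seq(18, 19.9, 0.1))
  truth_e <- eval_moments(hf$model, ge)
  pm_e <- predict_moments(fit, ge)
  dze <- z_from_measurement(truth_e$mu, pm_e$mu, pm_e$sigma, pm_e$nu)
  expect_lt(stats::median(abs(dze)), 0.12)
  # calibration of residual z-scores on the training data
  rz <- residual_zscores(fit)
  expect_lt(abs(mean(rz)), 0.03)
  expect_equal(stats::sd(rz), 1, tolerance = 0.03)
  # fresh data from the fitted model scores standard normal
  refit_model <- as_moment_curves(fit)
  d2 <- simulate_dataset(refit_model,
                         sampling_scheme(0.5, 0.05, 19.95, n = 4000),
                         seed = 22)
  z2 <- residual_zscores(fit, d2)
  expect_gt(stats::ks.test(z2, "pnorm")$p.value, 0.01)
  # y at the fitted median scores exactly zero
  pm5 <- predict_moments(fit, 5)
  expect_equal(residual_zscores(fit, data.frame(age = 5, y = pm5$mu)), 0,
               tolerance = 1e-12)
  expect_error(predict_moments(fit, 25), "range")
})

test_that("the lognormal special case agrees with an additive model on logs", {
  skip_if_not_installed("mgcv")
  set.seed(23)
  t <- stats::runif(3000, 0, 16)
  d <- data.frame(age = t, y = rbccg(exp(3 + 0.1 * sqrt(t)), 0.08, 0))
  fit <- fit_bccg(d, fit_config(nu_class = "constant"))
  g <- seq(1, 15, by = 0.5)
  gam_mu <- exp(stats::predict(mgcv::gam(log(y) ~ s(age, k = 20), data = d),
                               data.frame(age = g)))
  expect_lt(max(abs(predict_moments(fit, g)$mu / gam_mu - 1)), 0.005)
  expect_lt(abs(predict_moments(fit, 8)$nu), 0.6)
})

test_that("information criteria obey their identities", {
  fit <- height_fit()$fit
  ic3 <- information_criteria(fit, 3)
  icln <- information_criteria(fit, log(fit$n))
  expect_equal(icln$gaic, ic3$bic)
  expect_lt(ic3$gaic, ic3$bic)  # n > e^3
  expect_equal(ic3$edf_total, sum(fit$edf))
})

test_that("skewness curve class is selected by GAIC(3)", {
  set.seed(24)
  t <- stats::runif(2500, 0, 16)
  # truth: constant nu
  d <- data.frame(age = t, y = rbccg(50 + 3 * t, 0.08, 0.5))
  fit_auto <- fit_bccg(d, fit_config(xi = 1, nu_class = "auto"))
  gaics <- vapply(c("constant", "linear", "smooth"), function(cl)
    information_criteria(fit_bccg(d, fit_config(xi = 1, nu_class = cl)),
                         3)$gaic, numeric(1))
  expect_equal(information_criteria(fit_auto, 3)$gaic, min(gaics),
               tolerance = 1e-8)
  expect_identical(fit_auto$terms$nu$type, "constant")
})

test_that("penalized log-likelihood ascends under fixed smoothing", {
  hf <- height_fit()
  bf <- centdesign:::refit_resample(hf$fit, seq_len(hf$fit$n))
  expect_true(all(diff(bf$trace) > -1e-6))
})

test_that("the age-power hyperparameter is recovered from the data", {
  set.seed(25)
  t <- stats::runif(3000, 0, 16)
  d_sqrt <- data.frame(age = t, y = rbccg(50 + 20 * sqrt(t), 0.05, 1))
  d_lin <- data.frame(age = t, y = rbccg(50 + 5 * t, 0.05, 1))
  cfg <- fit_config(nu_class = "constant")
  xi_sqrt <- select_xi(d_sqrt, cfg)
  xi_lin <- select_xi(d_lin, cfg)
  expect_gte(xi_sqrt, 0.4); expect_lte(xi_sqrt, 0.6)
  expect_gte(xi_lin, 0.85); expect_lte(xi_lin, 1)
})

test_that("the analytic median SE_z band matches normal theory and scaling", {
  set.seed(26)
  d <- data.frame(age = rep(8, 1000), y = rbccg(rep(130, 1000), 0.05, 1))
  fit <- fit_bccg(d)
  se <- mu_se_z_curve(fit, 8)$se_z
  expect_rel(se, se_z_normal(0, 1000), 0.15)
  # quartering n doubles SE_z, approximately
  fx <- growth_fixture("height")
  ses <- vapply(c(7000, 1750), function(n) {
    dd <- simulate_dataset(fx, sampling_scheme(0.5, 0, 20, n = n),
                           seed = 27)
    ff <- fit_bccg(dd, fit_config(xi = 0.5, nu_class = "constant"))
    s <- mu_se_z_curve(ff, seq(2, 18, 0.5))$se_z
    expect_true(all(s > 0))
    exp(mean(log(s)))
  }, numeric(1))
  expect_gt(ses[2] / ses[1], 1.7)
  expect_lt(ses[2] / ses[1], 2.3)
})
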