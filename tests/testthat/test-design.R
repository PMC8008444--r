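dm <- design_model()

test_that("optimal age power matches the published flatness solutions", {
  expect_equal(round(optimal_lambda(dm, 0), 2), 0.38)
  expect_equal(round(optimal_lambda(dm, 0.67), 2), 0.45)
  expect_equal(round(optimal_lambda(dm, 1.33), 2), 0.60)
  expect_equal(round(optimal_lambda(dm, 2), 2), 0.76)
  expect_equal(round(optimal_lambda(dm, 2.67), 2), 0.90)
  expect_equal(round(optimal_lambda(dm, 1.88), 2), 0.73)
  # even in z, strictly increasing in |z|
  zs <- c(0, 0.67, 1.33, 2, 2.67)
  lam <- vapply(zs, function(z) optimal_lambda(dm, z), numeric(1))
  expect_equal(lam, vapply(-zs, function(z) optimal_lambda(dm, z),
                           numeric(1)))
  expect_true(all(diff(lam) > 0))
  expect_error(optimal_lambda(dm, 6), "infeasible")
})

test_that("predicted SE_z reproduces the published design values", {
  expect_equal(round(predict_se_z(dm, 0, 0.38), 3), 0.041)
  expect_equal(round(predict_se_z(dm, 2), 3), 0.066)
  expect_equal(round(predict_se_z(dm, 1.88), 3), 0.064)
  expect_equal(round(predict_se_z(dm, 2, n = 7200), 3), 0.065)
  expect_equal(round(predict_se_z(dm, 2, n = 93000), 3), 0.016)
  # monotone in |z| and in n
  expect_true(all(diff(vapply(c(0, 1, 2), function(z)
    predict_se_z(dm, z, 0.5), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(2000, 7200, 93000), function(n)
    predict_se_z(dm, 2, n = n), numeric(1))) < 0))
  expect_error(predict_se_z(dm, 0, lambda = 1.2), "lambda")
})

test_that("required sample size inverts the scaling law", {
  # published worked example: 97th height centile to SE_z 0.053
  n <- required_n(dm, 1.88, 0.053)
  expect_rel(n, 9910, 0.02)
  # fixed point at the reference size
  expect_equal(required_n(dm, 0, predict_se_z(dm, 0)), dm$n_ref)
  # halving the target multiplies n by 2^1.85
  expect_rel(required_n(dm, 0, 0.02) / required_n(dm, 0, 0.04), 2^1.85,
             0.001)
  expect_error(required_n(dm, 0, -1), "positive")
})

test_that("centile confidence intervals match the published rows", {
  ci <- centile_ci(0, predict_se_z(dm, 0, 0.38))
  expect_equal(round(unlist(ci), 1), c(lower = 46.7, upper = 53.3))
  ci2 <- centile_ci(-2, predict_se_z(dm, 2, n = 7200))
  expect_equal(round(unlist(ci2), 1), c(lower = 1.7, upper = 3.1))
  expect_equal(unlist(centile_ci(1, 0)),
               c(lower = 1, upper = 1) * 100 * stats::pnorm(1))
  # upper-centile interval is the mirror of the lower-centile one
  se <- 0.065
  expect_equal(centile_ci(2, se)$upper, 100 - centile_ci(-2, se)$lower)
  expect_equal(centile_ci(2, se)$lower, 100 - centile_ci(-2, se)$upper)
})

test_that("the design table reproduces published cells and shrinks with n", {
  tab <- design_table(dm)
  row <- tab[tab$n == 93000 & tab$z == -2, ]
  expect_equal(round(row$se_z, 3), 0.016)
  expect_equal(round(row$ci_lower, 1), 2.1)
  expect_equal(round(row$ci_upper, 1), 2.5)
  expect_equal(round(tab$se_z[tab$n == 2000 & tab$z == 0], 2), 0.08)
  for (zz in unique(tab$z)) {
    w <- tab$ci_upper[tab$z == zz] - tab$ci_lower[tab$z == zz]
    expect_true(all(diff(w[order(tab$n[tab$z == zz])]) < 0))
  }
})

test_that("the design regression is recovered from SE_z surfaces", {
  grid <- expand.grid(age = seq(2, 18, by = 0.1),
                      z_centile = c(-2.67, -2, -1.33, -0.67, 0, 0.67, 1.33,
                                    2, 2.67),
                      lambda = c(0.31, 0.5, 0.75, 1))
  zt <- log(1 + grid$z_centile^2 / 2)
  mu <- dm$b0 + dm$b_z * zt + dm$b_lambda * grid$lambda +
    (dm$b_age + dm$b_age_z * zt + dm$b_age_lambda * grid$lambda) *
    (grid$age - 10)
  # noiseless surfaces: exact coefficient recovery
  grid$se_z <- exp(mu)
  m1 <- fit_design_model(grid, n_ref = 6878)
  for (f in c("b0", "b_z", "b_lambda", "b_age", "b_age_z", "b_age_lambda"))
    expect_equal(m1[[f]], dm[[f]], tolerance = 1e-10)
  # multiplicative noise: recovery within 3 standard errors
  set.seed(31)
  grid$se_z <- exp(mu + stats::rnorm(nrow(grid), 0, 0.1))
  m2 <- fit_design_model(grid, n_ref = 6878)
  ses <- sqrt(diag(stats::vcov(attr(m2, "fit"))))
  truth <- c(dm$b0, dm$b_z, dm$b_lambda, dm$b_age, dm$b_age_z,
             dm$b_age_lambda)
  est <- c(m2$b0, m2$b_z, m2$b_lambda, m2$b_age, m2$b_age_z,
           m2$b_age_lambda)
  expect_true(all(abs(est - truth) <
                    3 * ses[c("(Intercept)", "zt", "lambda", "ac", "zt:ac",
                              "lambda:ac")]))
  # degenerate input: a single lambda cannot identify the model
  expect_error(fit_design_model(grid[grid$lambda == 0.5, ], n_ref = 6878),
               "distinct")
})

test_that("design model validation rejects impossible coefficients", {
  expect_error(design_model(b_age_lambda = 0.1), "negative")
  expect_error(design_model(n_ref = 0), "n_ref")
})
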