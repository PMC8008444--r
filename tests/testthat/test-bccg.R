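test_that("centile and z-score transforms are exact mutual inverses", {
  expect_equal(centile_from_z(0, mu = 50, sigma = 0.1, nu = 1), 50)
  expect_equal(centile_from_z(2, mu = 50, sigma = 0.1, nu = 0),
               50 * exp(0.2))
  expect_equal(centile_from_z(1, mu = 20, sigma = 0.15, nu = -0.5),
               20 * 0.925^-2)
  expect_equal(z_from_measurement(50, mu = 50, sigma = 0.1, nu = 0), 0)
  expect_equal(z_from_measurement(50 * exp(0.2), mu = 50, sigma = 0.1,
                                  nu = 0), 2)
  # round trip over a grid of z and nu
  z <- seq(-2.67, 2.67, length.out = 25)
  for (nu in c(-1, -0.3, 0, 0.7, 1)) {
    y <- centile_from_z(z, mu = 37, sigma = 0.12, nu = nu)
    expect_lt(max(abs(z_from_measurement(y, 37, 0.12, nu) - z)), 1e-10)
    expect_true(all(diff(y) > 0))  # strictly increasing in z
  }
})

test_that("transforms reject invalid parameters and out-of-domain inputs", {
  expect_error(centile_from_z(0, mu = -1, sigma = 0.1, nu = 1), "mu")
  expect_error(centile_from_z(0, mu = 50, sigma = 0, nu = 1), "sigma")
  # 1 + nu*sigma*z <= 0
  expect_error(centile_from_z(-3, mu = 50, sigma = 0.5, nu = 1), "domain")
  expect_error(z_from_measurement(-2, mu = 50, sigma = 0.1, nu = 1),
               "positive")
  expect_error(dbccg(0, mu = 50, sigma = 0.1, nu = 1), "positive")
})

test_that("normal-theory SE_z formula and its inverse match published values", {
  expect_equal(round(se_z_normal(0, 1000), 3), 0.032)
  expect_equal(round(se_z_normal(2, 1000), 3), 0.055)
  expect_equal(round(se_z_normal(1.88, 1000), 3), 0.053)
  # exact inverse and closed forms
  expect_equal(n_from_se(2, se_z_normal(2, 1000)), 1000)
  expect_equal(n_from_se(0, 0.1), 100)
  expect_equal(n_from_se(2.33, 0.05), (1 + 2.33^2 / 2) / 0.0025)
  # scale-free ratio sqrt(1 + z^2/2), identical for any n
  for (n in c(10, 1000, 1e6)) {
    expect_equal(se_z_normal(1.88, n) / se_z_normal(0, n),
                 sqrt(1 + 1.88^2 / 2))
  }
  expect_error(se_z_normal(0, 0), "at least 1")
  expect_error(n_from_se(0, 0), "positive")
})

test_that("sample size formula agrees with simulated centile precision", {
  # empirical SE of the Normal-theory 1st-centile estimate mean + z*SD at
  # the n the formula prescribes (the formula describes this estimator, not
  # the raw sample quantile, whose SE is larger)
  n <- round(n_from_se(-2.33, 0.05))
  set.seed(101)
  q <- replicate(500, { x <- stats::rnorm(n); mean(x) - 2.33 * stats::sd(x) })
  expect_rel(stats::sd(q), 0.05, 0.12)
})

test_that("BCCG density is normalized and has calibrated z-scores", {
  f <- function(y) dbccg(y, mu = 20, sigma = 0.1, nu = 0.5)
  expect_equal(stats::integrate(f, 1e-6, 200, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # small-sigma limit: close to Normal(mu, mu*sigma)
  mu <- 50; s <- 0.01
  for (y in mu + c(-2, 0, 2) * mu * s) {
    expect_equal(dbccg(y, mu, s, nu = 1, log = TRUE),
                 stats::dnorm(y, mu, mu * s, log = TRUE), tolerance = 1e-3)
  }
  set.seed(5)
  y <- rbccg(rep(20, 1e5), 0.1, 0.5)
  expect_lt(abs(mean(z_from_measurement(y, 20, 0.1, 0.5))), 0.01)
})

test_that("analytic scores match finite differences of the log density", {
  dl <- function(mu, sigma, nu, y, eps = 1e-4) {
    c(mu = (dbccg(y, mu + eps, sigma, nu, log = TRUE) -
              dbccg(y, mu - eps, sigma, nu, log = TRUE)) / (2 * eps),
      sigma = (dbccg(y, mu, sigma + eps, nu, log = TRUE) -
                 dbccg(y, mu, sigma - eps, nu, log = TRUE)) / (2 * eps),
      nu = (dbccg(y, mu, sigma, nu + eps, log = TRUE) -
              dbccg(y, mu, sigma, nu - eps, log = TRUE)) / (2 * eps))
  }
  for (p in list(c(50, 0.1, 1, 57), c(20, 0.15, -0.8, 16),
                 c(35, 0.05, 0.00002, 36))) {
    d <- centdesign:::bccg_derivs(p[4], p[1], p[2], p[3])
    num <- dl(p[1], p[2], p[3], p[4])
    expect_equal(d$mu$u, unname(num["mu"]), tolerance = 1e-4)
    # sigma score is held on the log-sigma scale
    expect_equal(d$sigma$u / p[2], unname(num["sigma"]), tolerance = 1e-4)
    expect_equal(d$nu$u, unname(num["nu"]), tolerance = 1e-4)
  }
})

test_that("random BCCG draws have the right distribution", {
  set.seed(6)
  y <- rbccg(rep(30, 1e5), 0.12, -0.4)
  z <- z_from_measurement(y, 30, 0.12, -0.4)
  expect_gt(stats::ks.test(z, "pnorm")$p.value, 0.01)
  # empirical 97.7th percentile matches the z = 2 centile
  q <- stats::quantile(y, stats::pnorm(2), names = FALSE)
  expect_rel(q, centile_from_z(2, 30, 0.12, -0.4), 0.005)
  # SE of an efficient median estimate matches normal theory (the moment
  # estimator (mean(y^nu))^(1/nu) is exactly mean-of-z on the z scale)
  set.seed(7)
  med_z <- replicate(400, {
    yy <- rbccg(rep(30, 500), 0.12, -0.4)
    z_from_measurement(mean(yy^-0.4)^(1 / -0.4), 30, 0.12, -0.4)
  })
  expect_rel(stats::sd(med_z), se_z_normal(0, 500), 0.15)
})

test_that("centile_spec carries the nine-centile chart convention", {
  cs <- centile_spec()
  expect_equal(cs$z, c(-2.67, -2, -1.33, -0.67, 0, 0.67, 1.33, 2, 2.67))
  expect_equal(cs$alpha, stats::pnorm(cs$z), tolerance = 1e-10)
  expect_equal(round(centile_spec(c(-2, 2))$centile, 1), c(2.3, 97.7))
})
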