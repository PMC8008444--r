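#' Design meta-regression model for centile precision
#'
#' The design layer rests on a meta-regression of bootstrapped log SE_z
#' curves on age (centred at 10 years), the centile term log(1 + z^2/2) and
#' the sample-composition age power lambda, with the two age interactions:
#' \deqn{\log SE_z = b_0 + b_z \log(1+z^2/2) + b_\lambda \lambda +
#'   (b_{age} + b_{age:z}\log(1+z^2/2) + b_{age:\lambda}\lambda)(age - 10).}
#' The packaged default coefficients are the published values estimated from
#' large-scale simulations off a reference of n = 6878 subjects aged 0-21
#' years, together with the empirical sample-size scaling law
#' \eqn{n \propto SE_z^{-1.85}}. [fit_design_model()] re-estimates the
#' coefficients from user-supplied SE_z curves without touching the
#' defaults.
#'
#' @param b0 intercept of log SE_z at the reference size.
#' @param b_z coefficient of log(1 + z^2/2).
#' @param b_lambda coefficient of the age power lambda.
#' @param b_age age main effect (per year).
#' @param b_age_z age x log(1 + z^2/2) interaction (per year).
#' @param b_age_lambda age x lambda interaction (per year); must be negative
#'   for the flatness condition to have a solution.
#' @param age_centre centring age in years.
#' @param n_ref sample size at which the regression was estimated.
#' @param scaling_exponent exponent of the sample-size scaling law.
#' @return an object of class \code{design_model}.
#' @examples
#' dm <- design_model()
#' optimal_lambda(dm, z = 0)       # 0.38
#' predict_se_z(dm, z = 0)         # 0.041
#' @export
design_model <- function(b0 = -3.088, b_z = 0.537, b_lambda = -0.283,
                         b_age = 0.0231, b_age_z = 0.0205,
                         b_age_lambda = -0.0604, age_centre = 10,
                         n_ref = 6878, scaling_exponent = 1.85) {
  if (b_age_lambda >= 0)
    stop("'b_age_lambda' must be negative (no flatness solution otherwise)",
         call. = FALSE)
  if (n_ref < 1 || scaling_exponent <= 0)
    stop("invalid 'n_ref' or 'scaling_exponent'", call. = FALSE)
  structure(list(b0 = b0, b_z = b_z, b_lambda = b_lambda, b_age = b_age,
                 b_age_z = b_age_z, b_age_lambda = b_age_lambda,
                 age_centre = age_centre, n_ref = n_ref,
                 scaling_exponent = scaling_exponent),
            class = "design_model")
}

#' @export
print.design_model <- function(x, ...) {
  cat("centile-precision design model (log SE_z regression)\n")
  cat(sprintf("  log SE_z = %.4g %+.4g log(1+z^2/2) %+.4g lambda\n",
              x$b0, x$b_z, x$b_lambda))
  cat(sprintf("           + (%.4g %+.4g log(1+z^2/2) %+.4g lambda) (age - %g)\n",
              x$b_age, x$b_age_z, x$b_age_lambda, x$age_centre))
  cat(sprintf("  reference n = %d; n scales as SE_z^-%.3g\n",
              x$n_ref, x$scaling_exponent))
  invisible(x)
}

#' Optimal sample-composition age power for a centile
#'
#' Solves the flatness condition: the three age terms of the design
#' regression sum to zero, so SE_z is constant across age. This gives
#' \code{lambda = (b_age + b_age_z * log(1 + z^2/2)) / (-b_age_lambda)},
#' an even function of z that increases with |z|: the median needs heavy
#' infant over-sampling (lambda 0.38) while the outer centiles need nearly
#' uniform ages (lambda 0.90 at |z| = 2.67).
#'
#' @param model a [design_model()].
#' @param z normal equivalent deviate of the design centile.
#' @return the optimal age power lambda, in (0, 1].
#' @export
optimal_lambda <- function(model = design_model(), z) {
  stopifnot(inherits(model, "design_model"))
  lam <- (model$b_age + model$b_age_z * log(1 + z^2 / 2)) /
    (-model$b_age_lambda)
  if (any(lam <= 0) || any(lam > 1))
    stop(sprintf("flatness condition gives lambda = %.3g outside (0, 1]: design infeasible",
                 lam[which(lam <= 0 | lam > 1)[1]]), call. = FALSE)
  lam
}

#' Predicted SE_z for a design
#'
#' The first three terms of the design regression give SE_z at the reference
#' sample size; other sample sizes are reached through the scaling law
#' \code{SE_z(n) = SE_z(n_ref) * (n_ref / n)^(1 / scaling_exponent)}.
#'
#' @param model a [design_model()].
#' @param z normal equivalent deviate of the centile.
#' @param lambda age power of the sample composition, in (0, 1]; defaults to
#'   the optimal value for \code{z}.
#' @param n sample size (default the model's reference size).
#' @return predicted standard error in z-score units.
#' @export
predict_se_z <- function(model = design_model(), z,
                         lambda = optimal_lambda(model, z),
                         n = model$n_ref) {
  stopifnot(inherits(model, "design_model"))
  if (any(lambda <= 0) || any(lambda > 1))
    stop("'lambda' must be in (0, 1]", call. = FALSE)
  if (any(n < 1)) stop("'n' must be at least 1", call. = FALSE)
  se_ref <- exp(model$b0 + model$b_z * log(1 + z^2 / 2) +
                  model$b_lambda * lambda)
  se_ref * (model$n_ref / n)^(1 / model$scaling_exponent)
}

#' Required sample size for a target centile precision
#'
#' Inverts the scaling law at the optimal sample composition:
#' \code{n = n_ref * (SE_z(n_ref) / target)^scaling_exponent}, rounded up.
#'
#' @param model a [design_model()].
#' @param z normal equivalent deviate of the design centile.
#' @param target_se required SE_z, positive.
#' @return integer sample size.
#' @examples
#' required_n(design_model(), z = 1.88, target_se = 0.053)
#' @export
required_n <- function(model = design_model(), z, target_se) {
  stopifnot(inherits(model, "design_model"))
  if (any(target_se <= 0)) stop("'target_se' must be positive", call. = FALSE)
  se_ref <- predict_se_z(model, z, n = model$n_ref)
  ceiling(model$n_ref * (se_ref / target_se)^model$scaling_exponent)
}

#' Confidence interval for a centile, in centile units
#'
#' The 95% interval for the deviate is z +/- 2 SE_z (multiplier exactly 2 by
#' convention); back-transforming through the normal CDF expresses it as
#' centile percentages.
#'
#' @param z normal equivalent deviate of the centile.
#' @param se_z its standard error in z-score units, non-negative.
#' @return data frame with columns \code{lower}, \code{upper} (percent).
#' @examples
#' centile_ci(0, 0.041)    # (46.7, 53.3)
#' @export
centile_ci <- function(z, se_z) {
  if (any(se_z < 0)) stop("'se_z' must be non-negative", call. = FALSE)
  data.frame(lower = 100 * stats::pnorm(z - 2 * se_z),
             upper = 100 * stats::pnorm(z + 2 * se_z))
}

#' Design table: precision and confidence intervals by sample size
#'
#' For each sample size and centile: the optimal age power, the SE_z
#' achieved at that size under the optimal composition, and the 95%
#' confidence interval in centile units. Centiles above the median follow by
#' symmetry (interval obtained by difference from 100).
#'
#' @param model a [design_model()].
#' @param n vector of sample sizes.
#' @param z deviates of the centiles (default the lower half of the standard
#'   chart set; upper centiles are their mirror images).
#' @return data frame with columns \code{n}, \code{z}, \code{centile},
#'   \code{lambda}, \code{se_z}, \code{ci_lower}, \code{ci_upper}.
#' @export
design_table <- function(model = design_model(),
                         n = c(2000, 3400, 7200, 12000, 26000, 93000),
                         z = c(0, -0.67, -1.33, -2, -2.67)) {
  rows <- expand.grid(z = z, n = n)[, 2:1]
  lam <- vapply(rows$z, function(zz) optimal_lambda(model, zz), numeric(1))
  se <- predict_se_z(model, rows$z, lam, rows$n)
  ci <- centile_ci(rows$z, se)
  data.frame(n = rows$n, z = rows$z, centile = 100 * stats::pnorm(rows$z),
             lambda = lam, se_z = se,
             ci_lower = ci$lower, ci_upper = ci$upper)
}

#' Refit the design meta-regression from SE_z curves
#'
#' Ordinary least squares of log SE_z on centred age, log(1 + z^2/2), lambda
#' and the two age interactions, fitted to a collection of SE_z curves
#' labelled by their centile deviate and sampling age power. At least two
#' distinct z and two distinct lambda values are required.
#'
#' @param curves data frame with columns \code{age}, \code{z_centile},
#'   \code{lambda}, \code{se_z} — e.g. several [sez_tidy()] outputs stacked,
#'   each given its scheme's lambda.
#' @param n_ref the sample size the curves were computed at.
#' @param window age window to use (default 2-18 years).
#' @param age_centre centring age.
#' @param scaling_exponent carried into the returned model.
#' @return a [design_model()] with refitted coefficients, plus attributes
#'   \code{fit} (the \code{lm} object) and \code{anova_ss} (sum of squares
#'   by term).
#' @export
fit_design_model <- function(curves, n_ref, window = c(2, 18),
                             age_centre = 10, scaling_exponent = 1.85) {
  stopifnot(all(c("age", "z_centile", "lambda", "se_z") %in% names(curves)))
  if (length(unique(curves$z_centile)) < 2 ||
      length(unique(curves$lambda)) < 2)
    stop("need at least two distinct z and two distinct lambda values",
         call. = FALSE)
  d <- curves[curves$age >= window[1] & curves$age <= window[2], ]
  d$logse <- log(d$se_z)
  d$zt <- log(1 + d$z_centile^2 / 2)
  d$ac <- d$age - age_centre
  fit <- stats::lm(logse ~ zt + lambda + ac + ac:zt + ac:lambda, data = d)
  co <- stats::coef(fit)
  if (any(!is.finite(co)))
    stop("design regression is rank deficient", call. = FALSE)
  model <- design_model(b0 = unname(co["(Intercept)"]),
                        b_z = unname(co["zt"]),
                        b_lambda = unname(co["lambda"]),
                        b_age = unname(co["ac"]),
                        b_age_z = unname(co["zt:ac"]),
                        b_age_lambda = unname(co["lambda:ac"]),
                        age_centre = age_centre, n_ref = n_ref,
                        scaling_exponent = scaling_exponent)
  ss <- suppressWarnings(stats::anova(fit))
  attr(model, "fit") <- fit
  attr(model, "anova_ss") <- stats::setNames(ss[["Sum Sq"]], rownames(ss))
  model
}

#' Find the age power that flattens the SE_z curve by simulation
#'
#' The full design loop: simulate a dataset from the base model under an
#' age^lambda composition, fit the BCCG model, estimate the chosen centile's
#' SE_z curve (bootstrap, or the analytic median band when z = 0), and
#' summarise it as the 2-18 year slope of log SE_z on age. The age power is
#' then root-found (bisection/secant on the slope) until the slope is within
#' tolerance of zero, i.e. the SE_z curve is essentially flat.
#'
#' @param base_model a [moment_curves()] base model.
#' @param z deviate of the centile whose precision is optimised.
#' @param n sample size per simulated dataset.
#' @param xi age power for the median curve in the fits (defaults to the
#'   base model's straightening power).
#' @param B bootstrap replicates per evaluation (default 100 for speed).
#' @param se_method \code{"bootstrap"} or \code{"analytic"} (median only).
#' @param nu_class skewness curve class used in the fits (a concrete class
#'   keeps evaluations comparable; default \code{"linear"}).
#' @param bracket initial lambda bracket.
#' @param slope_tol stop when |slope| is below this (log SE_z per year).
#' @param max_eval cap on the number of lambda evaluations.
#' @param reps datasets simulated per lambda evaluation; the slope used is
#'   their mean (averaging tames single-dataset noise in the trend).
#' @param seed optional integer seed.
#' @return list with \code{lambda} (the flattening age power), \code{slope}
#'   (the measured slope at the evaluation nearest the solution), and
#'   \code{path} (data frame of the lambda/slope evaluations).
#' @export
flatten_lambda <- function(base_model, z, n = 6878, xi = NULL, B = 100,
                           se_method = c("bootstrap", "analytic"),
                           nu_class = "linear",
                           bracket = c(0.2, 1), slope_tol = 0.005,
                           max_eval = 8, reps = 1, seed = NULL) {
  se_method <- match.arg(se_method)
  if (se_method == "analytic" && abs(z) > 1e-8)
    stop("the analytic SE_z band applies to the median only", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(xi)) xi <- straightening_power(base_model)
  grid <- seq(base_model$age_min, base_model$age_max, by = 0.1)
  slope_once <- function(lambda) {
    sch <- sampling_scheme(lambda, base_model$age_min, base_model$age_max,
                           n = n)
    d <- simulate_dataset(base_model, sch)
    fit <- fit_bccg(d, fit_config(xi = xi, nu_class = nu_class))
    g <- grid[grid >= min(d$age) & grid <= max(d$age)]
    tidy <- if (se_method == "analytic") {
      se <- mu_se_z_curve(fit, g)
      data.frame(age = se$age, z_centile = 0, se_z = se$se_z)
    } else {
      sez_tidy(bootstrap_se_curves(fit, z = z, B = B, grid = g))
    }
    sez_trend(tidy)$slope[1]
  }
  slope_at <- function(lambda)
    mean(vapply(seq_len(reps), function(r) slope_once(lambda), numeric(1)))
  evals <- data.frame(lambda = numeric(0), slope = numeric(0))
  eval_log <- function(lam) {
    s <- slope_at(lam)
    evals[nrow(evals) + 1, ] <<- c(lam, s)
    s
  }
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- eval_log(lo)
  s_hi <- eval_log(hi)
  # slope falls with lambda: heavy infant over-sampling (small lambda) gives
  # SE_z rising with age, uniform ages give it falling; root-finding only
  # needs the sign change over the bracket
  if (s_lo * s_hi > 0) {
    # no crossing inside the bracket: accept an endpoint only if it is
    # already flat within tolerance
    if (min(abs(c(s_lo, s_hi))) < slope_tol) {
      i <- which.min(abs(c(s_lo, s_hi)))
      return(list(lambda = c(lo, hi)[i], slope = c(s_lo, s_hi)[i],
                  path = evals))
    }
    stop("no sign change in the SE_z slope over the lambda bracket: design infeasible",
         call. = FALSE)
  }
  # regression-secant: the slope is close to linear in lambda (the design
  # meta-regression's age:lambda term), so the root of the least-squares
  # line through ALL evaluations is used both to propose the next lambda
  # and as the final estimate; pooling evaluations tames the simulation
  # noise of any single slope measurement
  line_root <- function() {
    co <- stats::coef(stats::lm(slope ~ lambda, data = evals))
    if (!is.finite(co[2]) || co[2] >= 0) return((lo + hi) / 2)
    unname(-co[1] / co[2])
  }
  root <- (lo + hi) / 2
  while (nrow(evals) < max_eval) {
    lam_new <- min(max(line_root(), lo + 0.01), hi - 0.01)
    s_new <- eval_log(lam_new)
    if (s_new * s_lo > 0) { lo <- lam_new; s_lo <- s_new }
    else { hi <- lam_new; s_hi <- s_new }
    root_new <- min(max(line_root(), bracket[1]), bracket[2])
    moved <- abs(root_new - root)
    root <- root_new
    if (moved < 0.02 && abs(s_new) < slope_tol) break
  }
  i_near <- which.min(abs(evals$lambda - root))
  list(lambda = root, slope = evals$slope[i_near], path = evals)
}
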