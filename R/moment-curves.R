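#' Age-varying BCCG moment curves (a base model)
#'
#' A \code{moment_curves} object holds smooth functions of age for the three
#' BCCG moments: the median mu(t), the generalised CV sigma(t) and the Box-Cox
#' power nu(t), over a closed age domain. It is the "base model" from which
#' datasets are simulated and against which z-scores are computed.
#'
#' @param mu_fun,sigma_fun,nu_fun functions of age (years) returning the
#'   corresponding moment; \code{mu_fun} and \code{sigma_fun} must be positive
#'   throughout the domain.
#' @param age_min,age_max age domain in decimal years (age 0 = birth).
#' @param label measurement name, e.g. \code{"height"}.
#' @param units measurement units, e.g. \code{"cm"}.
#' @return an object of class \code{moment_curves}.
#' @seealso [eval_moments()], [growth_fixture()], [read_lms_table()],
#'   [centile_table()]
#' @export
moment_curves <- function(mu_fun, sigma_fun, nu_fun, age_min, age_max,
                          label = "measurement", units = "") {
  stopifnot(is.function(mu_fun), is.function(sigma_fun), is.function(nu_fun),
            is.numeric(age_min), is.numeric(age_max), age_max > age_min)
  obj <- structure(
    list(mu_fun = mu_fun, sigma_fun = sigma_fun, nu_fun = nu_fun,
         age_min = age_min, age_max = age_max, label = label, units = units),
    class = "moment_curves")
  probe <- seq(age_min, age_max, length.out = 101)
  m <- eval_moments(obj, probe)
  if (any(m$mu <= 0)) stop("mu curve must be positive over the age domain",
                           call. = FALSE)
  if (any(m$sigma <= 0)) stop("sigma curve must be positive over the age domain",
                              call. = FALSE)
  obj
}

#' @export
print.moment_curves <- function(x, ...) {
  cat("BCCG moment curves:", x$label,
      if (nzchar(x$units)) paste0("(", x$units, ")") else "", "\n")
  cat(sprintf("  age domain: %.3g to %.3g years\n", x$age_min, x$age_max))
  m <- eval_moments(x, c(x$age_min, (x$age_min + x$age_max) / 2, x$age_max))
  cat(sprintf("  mu: %.4g .. %.4g   sigma: %.4g .. %.4g   nu: %.3g .. %.3g\n",
              min(m$mu), max(m$mu), min(m$sigma), max(m$sigma),
              min(m$nu), max(m$nu)))
  invisible(x)
}

#' Evaluate moment curves at given ages
#'
#' @param model a \code{moment_curves} object.
#' @param ages vector of ages (years) inside the model's domain; evaluation
#'   outside the domain is an error (no extrapolation).
#' @return data frame with columns \code{age}, \code{mu}, \code{sigma},
#'   \code{nu}.
#' @export
eval_moments <- function(model, ages) {
  stopifnot(inherits(model, "moment_curves"))
  tol <- 1e-9 * max(1, abs(model$age_max))
  if (any(ages < model$age_min - tol) || any(ages > model$age_max + tol))
    stop(sprintf("ages outside model domain [%g, %g]",
                 model$age_min, model$age_max), call. = FALSE)
  ages <- pmin(pmax(ages, model$age_min), model$age_max)
  data.frame(age = ages, mu = model$mu_fun(ages),
             sigma = model$sigma_fun(ages), nu = model$nu_fun(ages))
}

# Shape-preserving interpolator through (x, y) anchors; monotone cubic
# Hermite (Fritsch-Carlson) so linear-in-between monotone sections stay
# monotone and M never dips negative between positive anchors.
interp_fun <- function(x, y) {
  if (length(x) == 1) {
    y0 <- y[1]
    return(function(t) rep_len(y0, length(t)))
  }
  if (length(x) < 4) return(stats::approxfun(x, y, rule = 2))
  f <- stats::splinefun(x, y, method = "monoH.FC")
  function(t) f(t)
}

#' Read and write LMS reference tables
#'
#' LMS reference tables are the standard exchange format for growth
#' references (WHO/CDC layout): a CSV with columns \code{age}, \code{L}
#' (Box-Cox power nu), \code{M} (median mu) and \code{S} (generalised CV
#' sigma), one row per tabulated age. Header names are matched
#' case-insensitively. Between tabulated rows the curves are interpolated by
#' shape-preserving monotone cubics, so centiles do not kink and M cannot dip
#' negative between positive rows. The model domain is the table's age span.
#'
#' @param path file path of the CSV table.
#' @param model a \code{moment_curves} object (for writing).
#' @param ages age grid at which to tabulate the model.
#' @param label,units passed to the resulting \code{moment_curves}.
#' @param digits significant digits written (default 6).
#' @return \code{read_lms_table} returns a \code{moment_curves};
#'   \code{write_lms_table} returns \code{path} invisibly.
#' @export
read_lms_table <- function(path, label = "measurement", units = "") {
  tab <- utils::read.csv(path, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("age", "l", "m", "s")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("LMS table is missing column(s): ",
         paste(toupper(miss), collapse = ", "), call. = FALSE)
  tab <- tab[need]
  if (any(!is.finite(as.matrix(tab))))
    stop("LMS table contains non-numeric or missing values", call. = FALSE)
  bad <- which(diff(tab$age) <= 0)
  if (length(bad))
    stop("LMS table ages must be strictly increasing (row ", bad[1] + 1, ")",
         call. = FALSE)
  bad <- which(tab$m <= 0 | tab$s <= 0)
  if (length(bad))
    stop("LMS table M and S must be positive (row ", bad[1], ")",
         call. = FALSE)
  moment_curves(interp_fun(tab$age, tab$m), interp_fun(tab$age, tab$s),
                interp_fun(tab$age, tab$l),
                age_min = min(tab$age), age_max = max(tab$age),
                label = label, units = units)
}

#' @rdname read_lms_table
#' @export
write_lms_table <- function(model, ages, path, digits = 6) {
  m <- eval_moments(model, ages)
  out <- data.frame(age = signif(m$age, digits), L = signif(m$nu, digits),
                    M = signif(m$mu, digits), S = signif(m$sigma, digits))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Anchor tables for the synthetic base models. Values are realistic boys'
# anthropometry on [0, 20] years: mu steep in infancy then decelerating, a
# mild pubertal inflection for height/weight, slowly varying sigma and nu.
fixture_anchors <- list(
  height = list(
    units = "cm",
    mu = cbind(age = c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11,
                       12, 13, 14, 15, 16, 17, 18, 19, 20),
               val = c(51, 62, 68, 76, 82, 87.5, 95, 103, 110, 117, 123, 129,
                       135, 140, 145, 151, 157, 165, 172, 177, 180, 182, 183,
                       183.5)),
    sigma = cbind(age = c(0, 1, 5, 10, 13, 16, 20),
                  val = c(0.037, 0.033, 0.040, 0.043, 0.047, 0.042, 0.038)),
    nu = cbind(age = c(0, 20), val = c(1, 1))),
  weight = list(
    units = "kg",
    mu = cbind(age = c(0, 0.25, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12,
                       13, 14, 15, 16, 17, 18, 19, 20),
               val = c(3.5, 6.0, 7.6, 9.7, 12.2, 14.3, 16.3, 18.3, 20.5, 23,
                       25.5, 28.5, 31.5, 35, 39, 44, 50, 56, 61, 65, 68, 70,
                       71.5)),
    sigma = cbind(age = c(0, 1, 5, 10, 14, 18, 20),
                  val = c(0.14, 0.11, 0.13, 0.17, 0.19, 0.16, 0.15)),
    nu = cbind(age = c(0, 5, 10, 15, 20),
               val = c(1.0, 0.3, -0.1, -0.3, -0.2))),
  bmi = list(
    units = "kg/m^2",
    mu = cbind(age = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9,
                       10, 12, 14, 16, 18, 20),
               val = c(13.3, 15.9, 16.9, 17.2, 17.2, 16.8, 16.4, 15.9, 15.6,
                       15.4, 15.4, 15.5, 15.8, 16.1, 16.5, 17.5, 18.7, 19.8,
                       20.8, 21.5)),
    sigma = cbind(age = c(0, 1, 5, 10, 15, 20),
                  val = c(0.08, 0.07, 0.075, 0.11, 0.13, 0.12)),
    nu = cbind(age = c(0, 3, 8, 13, 20),
               val = c(0.9, -0.3, -1.2, -1.6, -1.3))),
  headcirc = list(
    units = "cm",
    mu = cbind(age = c(0, 0.25, 0.5, 1, 2, 3, 4, 5, 7, 10, 13, 16, 18, 20),
               val = c(35, 41, 43.5, 46.3, 48.3, 49.5, 50.2, 50.8, 51.5, 52.5,
                       53.5, 55, 55.7, 56)),
    sigma = cbind(age = c(0, 2, 10, 20),
                  val = c(0.031, 0.028, 0.028, 0.029)),
    nu = cbind(age = c(0, 10, 20), val = c(1.2, 0.8, 0.5))))

#' Synthetic base models for boys' anthropometry
#'
#' Deterministic, documented moment-curve sets on [0, 20] years qualitatively
#' emulating boys' weight, height, BMI and head-circumference references:
#' medians steep in infancy then decelerating (with a mild pubertal
#' inflection for height and weight, and the infancy peak plus adiposity
#' rebound for BMI), with slowly varying CV and skewness curves. The curves
#' are shape-preserving cubics through fixed anchor tables; they are
#' synthetic and make no claim of numerical equality with any published
#' reference.
#'
#' @param kind one of \code{"weight"}, \code{"height"}, \code{"bmi"},
#'   \code{"headcirc"}.
#' @return a \code{moment_curves} object on [0, 20] years.
#' @examples
#' fx <- growth_fixture("height")
#' eval_moments(fx, c(0, 1, 10, 20))
#' @export
growth_fixture <- function(kind = c("weight", "height", "bmi", "headcirc")) {
  kind <- match.arg(kind)
  a <- fixture_anchors[[kind]]
  moment_curves(interp_fun(a$mu[, 1], a$mu[, 2]),
                interp_fun(a$sigma[, 1], a$sigma[, 2]),
                interp_fun(a$nu[, 1], a$nu[, 2]),
                age_min = 0, age_max = 20, label = kind, units = a$units)
}

#' Age power that straightens a median curve
#'
#' Finds the age power lambda for which the model's median curve has least
#' curvature when plotted against transformed age (rescaled as
#' \code{age^lambda * age_max^(1-lambda)} so the axis keeps the same span for
#' every lambda): the integrated squared second derivative of mu against
#' transformed age is minimized over a lambda grid. Transforming age this way
#' reduces the global curvature the median spline has to model.
#'
#' @param model a \code{moment_curves} object.
#' @param lambda_grid candidate powers.
#' @return the curvature-minimizing lambda.
#' @export
straightening_power <- function(model, lambda_grid = seq(0.05, 1, by = 0.01)) {
  ages <- seq(model$age_min + 1e-6, model$age_max, length.out = 401)
  mu <- eval_moments(model, ages)$mu
  amax <- model$age_max
  curv <- vapply(lambda_grid, function(lam) {
    s <- ages^lam * amax^(1 - lam)
    sg <- seq(min(s), max(s), length.out = 401)
    mg <- stats::approx(s, mu, xout = sg)$y
    h <- sg[2] - sg[1]
    sum((diff(mg, differences = 2) / h^2)^2) * h
  }, numeric(1))
  lambda_grid[which.min(curv)]
}

#' Tabulate centiles of a base model
#'
#' Evaluates measurement centiles of a moment-curve model over an age grid.
#' The default centile set is the standard chart convention of nine centiles
#' spaced two-thirds of a z-score apart (z from -2.67 to 2.67).
#'
#' @param model a \code{moment_curves} object.
#' @param z normal equivalent deviates of the centiles wanted.
#' @param ages age grid inside the model domain.
#' @return data frame with column \code{age} then one column per centile
#'   (named \code{z-2}, \code{z0}, ...), strictly increasing across each row.
#' @export
centile_table <- function(model, z = centile_z_set(),
                          ages = seq(model$age_min, model$age_max,
                                     length.out = 101)) {
  m <- eval_moments(model, ages)
  cols <- vapply(z, function(zz) centile_from_z(zz, m$mu, m$sigma, m$nu),
                 numeric(length(ages)))
  cols <- matrix(cols, nrow = length(ages))
  colnames(cols) <- paste0("z", z)
  cbind(data.frame(age = ages), as.data.frame(cols))
}
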