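#' The Box-Cox Cole-Green (LMS) distribution
#'
#' The BCCG distribution underlies the LMS method for growth reference
#' centiles. A positive measurement \code{y} at a given age is described by
#' three parameters: the median \code{mu}, the generalised coefficient of
#' variation \code{sigma} (so the generalised SD is \code{mu * sigma}) and the
#' Box-Cox skewness power \code{nu}. After the Box-Cox transform the
#' measurement is standard normal, so centiles and z-scores interconvert in
#' closed form:
#' \deqn{C_{100\alpha} = \mu (1 + \nu\sigma z_\alpha)^{1/\nu} \quad (\nu \ne 0),
#'       \qquad C_{100\alpha} = \mu e^{\sigma z_\alpha} \quad (\nu = 0)}
#' and inversely
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\sigma} \quad (\nu \ne 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0).}
#'
#' The density ignores the (negligible for moderate \code{sigma * |nu|})
#' truncation of \code{y} to positive values, as is standard LMS practice.
#'
#' @param y vector of positive measurements.
#' @param z vector of z-scores (normal equivalent deviates).
#' @param mu median, positive, recycled against \code{z}/\code{y}.
#' @param sigma generalised coefficient of variation, positive.
#' @param nu Box-Cox power (real; 0 gives the lognormal case).
#' @param log logical; return the log density?
#'
#' @return \code{centile_from_z} returns measurements, \code{z_from_measurement}
#'   returns z-scores, \code{dbccg} returns (log) density values and
#'   \code{rbccg} returns random measurements, one per parameter set.
#'
#' @examples
#' centile_from_z(0, mu = 50, sigma = 0.1, nu = 1)        # the median: 50
#' centile_from_z(2, mu = 50, sigma = 0.1, nu = 0)        # 50 * exp(0.2)
#' z_from_measurement(61.07, mu = 50, sigma = 0.1, nu = 0)
#' @name bccg
NULL

check_bccg_params <- function(mu, sigma, nu) {
  if (any(!is.finite(mu)) || any(!is.finite(sigma)) || any(!is.finite(nu)))
    stop("BCCG parameters must be finite", call. = FALSE)
  if (any(mu <= 0)) stop("BCCG 'mu' must be positive", call. = FALSE)
  if (any(sigma <= 0)) stop("BCCG 'sigma' must be positive", call. = FALSE)
  invisible(TRUE)
}

#' @rdname bccg
#' @export
centile_from_z <- function(z, mu, sigma, nu) {
  check_bccg_params(mu, sigma, nu)
  n <- max(length(z), length(mu), length(sigma), length(nu))
  z <- rep_len(z, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  nz <- nu != 0
  if (any(nz)) {
    base <- 1 + nu[nz] * sigma[nz] * z[nz]
    if (any(base <= 0))
      stop("z outside BCCG domain: 1 + nu*sigma*z must be positive",
           call. = FALSE)
    out[nz] <- mu[nz] * base^(1 / nu[nz])
  }
  if (any(!nz)) out[!nz] <- mu[!nz] * exp(sigma[!nz] * z[!nz])
  out
}

#' @rdname bccg
#' @export
z_from_measurement <- function(y, mu, sigma, nu) {
  check_bccg_params(mu, sigma, nu)
  if (any(y <= 0)) stop("measurements must be positive", call. = FALSE)
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  nz <- nu != 0
  if (any(nz))
    out[nz] <- ((y[nz] / mu[nz])^nu[nz] - 1) / (nu[nz] * sigma[nz])
  if (any(!nz)) out[!nz] <- log(y[!nz] / mu[!nz]) / sigma[!nz]
  out
}

#' @rdname bccg
#' @export
dbccg <- function(y, mu, sigma, nu, log = FALSE) {
  check_bccg_params(mu, sigma, nu)
  if (any(y <= 0)) stop("measurements must be positive", call. = FALSE)
  z <- z_from_measurement(y, mu, sigma, nu)
  # density of y when z is standard normal; Jacobian dz/dy = (y/mu)^nu/(sigma*y)
  ll <- -0.5 * z^2 - 0.5 * log(2 * pi) + nu * log(y / mu) - log(sigma) - log(y)
  if (log) ll else exp(ll)
}

#' @rdname bccg
#' @export
rbccg <- function(mu, sigma, nu) {
  n <- max(length(mu), length(sigma), length(nu))
  # uniform proportion -> normal equivalent deviate -> measurement
  z <- stats::qnorm(stats::runif(n))
  centile_from_z(z, mu, sigma, nu)
}

#' Normal-theory precision of a sample centile
#'
#' For a single age group of \code{n} normally distributed measurements, the
#' standard error of the 100a'th sample centile, expressed in z-score units
#' (SE in measurement units divided by the SD), is
#' \deqn{SE_z = \sqrt{(1 + z_\alpha^2/2)/n}.}
#' It does not involve the mean or SD, so it applies to any measurement.
#' \code{n_from_se} inverts the formula to give the single-age-group sample
#' size achieving a target \eqn{SE_z}.
#'
#' @param z_alpha normal equivalent deviate of the centile (0 for the median,
#'   2 for the rounded 2nd/98th centiles, and so on).
#' @param n sample size (at one age), at least 1.
#' @param se_z target standard error in z-score units, positive.
#' @return \code{se_z_normal}: the standard error in z-score units.
#'   \code{n_from_se}: the (non-integer) sample size.
#' @examples
#' se_z_normal(0, 1000)   # 0.0316
#' se_z_normal(2, 1000)   # 0.0548
#' n_from_se(2, 0.0548)   # about 1000
#' @export
se_z_normal <- function(z_alpha, n) {
  if (any(n < 1)) stop("'n' must be at least 1", call. = FALSE)
  sqrt((1 + z_alpha^2 / 2) / n)
}

#' @rdname se_z_normal
#' @export
n_from_se <- function(z_alpha, se_z) {
  if (any(se_z <= 0)) stop("'se_z' must be positive", call. = FALSE)
  (1 + z_alpha^2 / 2) / se_z^2
}

#' Centile specifications
#'
#' Build a table of centile specifications from normal equivalent deviates,
#' including the chart convention of nine centiles spaced two-thirds of a
#' z-score apart (0.4th to 99.6th), where z = +/-2 is called the 2nd/98th
#' centile and z = +/-2.67 the 0.4th/99.6th.
#'
#' @param z vector of normal equivalent deviates.
#' @return data frame with columns \code{z}, \code{alpha} (proportion) and
#'   \code{centile} (percentage, \code{100 * alpha}).
#' @examples
#' centile_spec()       # the standard nine-centile set
#' centile_spec(c(-2, 0, 2))
#' @export
centile_spec <- function(z = centile_z_set()) {
  data.frame(z = z, alpha = stats::pnorm(z), centile = 100 * stats::pnorm(z))
}

#' @rdname centile_spec
#' @export
centile_z_set <- function() {
  c(-2.67, -2, -1.33, -0.67, 0, 0.67, 1.33, 2, 2.67)
}
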