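#' Bootstrap SE_z curves for centiles
#'
#' Estimates standard-error curves, on the z-score scale, for arbitrary
#' centiles of a fitted BCCG model. Rows of the data are resampled with
#' replacement, the model refitted (holding the smoothing parameters, age
#' power xi and curve classes fixed at the base fit's values), and each
#' requested centile evaluated on the age grid. The replicate centiles are
#' converted to z-scores using the ORIGINAL fit's moment curves, and the SD
#' across replicates at each grid age is the SE_z curve.
#'
#' @param fit a converged [fit_bccg()] on the study data.
#' @param z normal equivalent deviates of the centiles wanted (default the
#'   standard nine-centile set).
#' @param B number of bootstrap replicates (at least 50; 500 matches common
#'   practice, smaller values are used for quick runs).
#' @param grid age grid (default the fitted range at 0.1-year steps).
#' @param stratify optional vector of group break ages: resampling is then
#'   done within age strata instead of over all rows (off by default).
#' @param seed optional integer seed.
#' @return an object of class \code{sez_curve}: list with \code{age} (grid),
#'   \code{z}, matrix \code{se_z} (grid x centiles), \code{B},
#'   \code{B_used}, \code{n}, \code{seed}.
#' @seealso [sez_trend()]
#' @export
bootstrap_se_curves <- function(fit, z = centile_z_set(), B = 500,
                                grid = NULL, stratify = NULL, seed = NULL) {
  stopifnot(inherits(fit, "bccg_fit"))
  if (B < 50) stop("'B' must be at least 50", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) {
    grid <- seq(fit$age_range[1], fit$age_range[2], by = 0.1)
    if (diff(fit$age_range) < 1e-8) grid <- fit$age_range[1]
  }
  n <- fit$n
  m0 <- predict_moments(fit, grid)
  strata <- if (!is.null(stratify))
    findInterval(fit$data$age, stratify, all.inside = TRUE)
  acc <- array(NA_real_, dim = c(length(grid), length(z), B))
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- if (is.null(strata)) sample.int(n, n, replace = TRUE)
    else unlist(lapply(split(seq_len(n), strata), function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]),
      use.names = FALSE)
    rep_z <- tryCatch({
      bf <- refit_resample(fit, idx)
      mu_b <- drop(term_design(bf$terms$mu, grid^fit$xi) %*%
                     bf$terms$mu$beta)
      sg_b <- exp(drop(term_design(bf$terms$sigma, grid) %*%
                         bf$terms$sigma$beta))
      nu_b <- drop(term_design(bf$terms$nu, grid) %*% bf$terms$nu$beta)
      vapply(z, function(zz) {
        cent <- centile_from_z(zz, mu_b, sg_b, nu_b)
        z_from_measurement(cent, m0$mu, m0$sigma, m0$nu)
      }, numeric(length(grid)))
    }, error = function(e) NULL)
    if (is.null(rep_z)) failed <- failed + 1L
    else acc[, , b] <- rep_z
  }
  if (failed > 0.1 * B)
    stop(sprintf("%d of %d bootstrap replicates failed", failed, B),
         call. = FALSE)
  se <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
  colnames(se) <- paste0("z", z)
  structure(list(age = grid, z = z, se_z = se, B = B,
                 B_used = B - failed, n = n, seed = seed),
            class = "sez_curve")
}

#' @export
print.sez_curve <- function(x, ...) {
  cat(sprintf("bootstrap SE_z curves: %d ages x %d centiles, B = %d (%d used), n = %d\n",
              length(x$age), length(x$z), x$B, x$B_used, x$n))
  cat(sprintf("  SE_z range %.4f to %.4f\n", min(x$se_z), max(x$se_z)))
  invisible(x)
}

#' Tidy export of an SE_z curve set
#'
#' @param curve an \code{sez_curve}.
#' @return data frame with columns \code{age}, \code{z_centile},
#'   \code{se_z}.
#' @export
sez_tidy <- function(curve) {
  stopifnot(inherits(curve, "sez_curve"))
  data.frame(age = rep(curve$age, times = length(curve$z)),
             z_centile = rep(curve$z, each = length(curve$age)),
             se_z = as.vector(curve$se_z))
}

#' Linear-trend summary of SE_z curves
#'
#' Each centile's SE_z curve is summarised as a linear trend of log SE_z on
#' age, restricted to a window (default 2-18 years) to minimise edge
#' effects, with age centred at 10 years. A flat trend (slope 0) is the
#' optimal-design condition.
#'
#' @param curve an \code{sez_curve}, or a data frame with columns \code{age},
#'   \code{z_centile}, \code{se_z}.
#' @param window age window, default \code{c(2, 18)}.
#' @param age_centre centring age (default 10 years).
#' @return data frame with columns \code{z}, \code{intercept}, \code{slope}
#'   (log SE_z units; slope per year).
#' @export
sez_trend <- function(curve, window = c(2, 18), age_centre = 10) {
  tidy <- if (inherits(curve, "sez_curve")) sez_tidy(curve) else curve
  stopifnot(all(c("age", "z_centile", "se_z") %in% names(tidy)))
  if (min(tidy$age) > window[1] + 1e-8 || max(tidy$age) < window[2] - 1e-8)
    stop("SE_z grid does not cover the trend window", call. = FALSE)
  tidy <- tidy[tidy$age >= window[1] & tidy$age <= window[2], ]
  out <- do.call(rbind, lapply(split(tidy, tidy$z_centile), function(d) {
    co <- stats::coef(stats::lm(log(se_z) ~ I(age - age_centre), data = d))
    data.frame(z = d$z_centile[1], intercept = unname(co[1]),
               slope = unname(co[2]))
  }))
  rownames(out) <- NULL
  out[order(out$z), ]
}
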