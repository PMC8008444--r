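# P-spline machinery: cubic B-spline bases on equally spaced knots with a
# difference penalty on adjacent coefficients (Eilers-Marx), fitted by
# penalized weighted least squares. Smoothing parameters are updated by a
# local maximum-likelihood (Schall-type) step, or chosen to match a target
# effective dimension.

ps_knots <- function(xl, xr, nseg, deg = 3) {
  if (xr <= xl) xr <- xl + 1e-8
  dx <- (xr - xl) / nseg
  seq(xl - deg * dx, xr + deg * dx, by = dx)
}

ps_design <- function(x, knots, deg = 3) {
  splines::splineDesign(knots, x, ord = deg + 1, outer.ok = TRUE)
}

diff_penalty <- function(k, order = 2) {
  if (k <= order) return(matrix(0, k, k))
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

# Build a smooth/linear/constant term definition over covariate x.
# 'trans' is the covariate transform (age power for the median curve).
make_term <- function(x, type = c("smooth", "linear", "constant"),
                      nseg = 20, deg = 3, penalty_order = 2) {
  type <- match.arg(type)
  if (length(unique(x)) < 4 && type != "constant") type <- "constant"
  if (type == "constant") {
    return(list(type = type, B = matrix(1, length(x), 1),
                P = matrix(0, 1, 1), lambda = 0, pord = 0))
  }
  ctr <- mean(x); scl <- max(stats::sd(x), 1e-8)
  if (type == "linear") {
    return(list(type = type, ctr = ctr, scl = scl,
                B = cbind(1, (x - ctr) / scl),
                P = matrix(0, 2, 2), lambda = 0, pord = 0))
  }
  knots <- ps_knots(min(x), max(x), nseg, deg)
  list(type = type, deg = deg, knots = knots, xmin = min(x), xmax = max(x),
       B = ps_design(x, knots, deg),
       P = diff_penalty(nseg + deg, penalty_order),
       lambda = 10, pord = penalty_order)
}

# Evaluate a term's basis at new covariate values.
term_design <- function(term, x) {
  switch(term$type,
         constant = matrix(1, length(x), 1),
         linear   = cbind(1, (x - term$ctr) / term$scl),
         smooth   = ps_design(pmin(pmax(x, term$xmin), term$xmax),
                              term$knots, term$deg))
}

# Penalized WLS solve for one term given working response zw and weights w.
# Returns coefficients, fitted values, edf and the k x k pieces needed for
# smoothing updates and covariances.
pwls_solve <- function(B, P, w, zw, lambda) {
  sw <- sqrt(w)
  BtWB <- crossprod(B * sw)
  BtWz <- crossprod(B, w * zw)
  M <- BtWB + lambda * P
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    M <- M + diag(1e-8 * max(diag(BtWB), 1), ncol(B))
    R <- chol(M)
  }
  beta <- backsolve(R, forwardsolve(t(R), BtWz))
  Minv <- chol2inv(R)
  edf <- sum(Minv * BtWB)            # tr(M^-1 BtWB)
  list(beta = drop(beta), edf = edf, BtWB = BtWB, BtWz = BtWz, Minv = Minv)
}

# Local-ML (Schall) update of the smoothing parameter for a smooth term.
lambda_ml_update <- function(sol, B, P, w, zw, pord, lambda) {
  fitted <- drop(B %*% sol$beta)
  n <- length(zw)
  rss <- sum(w * (zw - fitted)^2)
  sig2 <- rss / max(n - sol$edf, 1)
  pen <- drop(crossprod(sol$beta, P %*% sol$beta))
  df_pen <- sol$edf - pord
  if (pen <= 1e-12 || df_pen <= 1e-3) return(min(lambda * 10, 1e7))
  tau2 <- pen / df_pen
  min(max(sig2 / tau2, 1e-4), 1e7)
}

# Choose lambda so the term's edf matches a target (monotone in lambda).
lambda_for_edf <- function(B, P, w, target_edf) {
  sw <- sqrt(w)
  BtWB <- crossprod(B * sw)
  edf_at <- function(loglam) {
    M <- BtWB + 10^loglam * P
    sum(chol2inv(chol(M + diag(1e-10, ncol(B)))) * BtWB) - target_edf
  }
  lo <- -4; hi <- 8
  flo <- edf_at(lo); fhi <- edf_at(hi)
  if (flo <= 0) return(10^lo)
  if (fhi >= 0) return(10^hi)
  10^stats::uniroot(edf_at, c(lo, hi), tol = 1e-3)$root
}
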