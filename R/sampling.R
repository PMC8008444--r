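#' Sample composition schemes on the age^lambda scale
#'
#' A sampling scheme describes the age distribution (sample composition) of a
#' cross-sectional reference study: ages are uniform on the transformed scale
#' f(age) = age^lambda, so lambda = 1 gives uniform ages and lambda < 1
#' over-samples infancy (the smaller lambda, the more so). Optional edge
#' multipliers inflate the first and last age groups to counter edge effects,
#' and optional group breaks switch to a grouped design.
#'
#' @param lambda age power, in (0, 1].
#' @param age_min,age_max age range in years, \code{age_min >= 0}.
#' @param n total number of subjects.
#' @param edge_low,edge_high multipliers (>= 1) applied to the first/last age
#'   group before renormalizing counts to \code{n} (grouped designs only).
#' @param breaks optional strictly increasing group boundary ages spanning
#'   \code{[age_min, age_max]}.
#' @return an object of class \code{sampling_scheme}.
#' @seealso [sample_ages()], [nagegp()], [simulate_dataset()]
#' @export
sampling_scheme <- function(lambda, age_min = 0, age_max = 20, n = 1000,
                            edge_low = 1, edge_high = 1, breaks = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda > 1)
    stop("'lambda' must be in (0, 1]", call. = FALSE)
  if (age_min < 0 || age_max <= age_min)
    stop("need 0 <= age_min < age_max", call. = FALSE)
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (edge_low < 1 || edge_high < 1)
    stop("edge multipliers must be >= 1", call. = FALSE)
  if (!is.null(breaks)) {
    if (any(diff(breaks) <= 0) || length(breaks) < 2)
      stop("'breaks' must be strictly increasing", call. = FALSE)
    if (abs(breaks[1] - age_min) > 1e-8 ||
        abs(breaks[length(breaks)] - age_max) > 1e-8)
      stop("'breaks' must span [age_min, age_max]", call. = FALSE)
  }
  structure(list(lambda = lambda, age_min = age_min, age_max = age_max,
                 n = as.integer(round(n)), edge_low = edge_low,
                 edge_high = edge_high, breaks = breaks),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("age^lambda sampling scheme: lambda = %.3g, ages [%g, %g], n = %d\n",
              x$lambda, x$age_min, x$age_max, x$n))
  if (!is.null(x$breaks))
    cat("  grouped:", length(x$breaks) - 1, "age groups\n")
  invisible(x)
}

#' Draw measurement ages uniform on the age^lambda scale
#'
#' Inverse-transform sampling: draw uniform deviates between
#' \code{age_min^lambda} and \code{age_max^lambda} and back-transform with
#' the power \code{1/lambda}. The resulting age CDF is
#' \code{(t^lambda - age_min^lambda) / (age_max^lambda - age_min^lambda)}.
#'
#' @param scheme a \code{sampling_scheme} (ungrouped).
#' @param n number of ages (default the scheme's \code{n}).
#' @return vector of ages in \code{[age_min, age_max]}.
#' @export
sample_ages <- function(scheme, n = scheme$n) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  lo <- scheme$age_min^scheme$lambda
  hi <- scheme$age_max^scheme$lambda
  stats::runif(n, lo, hi)^(1 / scheme$lambda)
}

#' Allocate subjects to age groups under an age^lambda design
#'
#' Splits the scheme's \code{n} subjects across age groups in proportion to
#' the age^lambda measure of each group, \code{b^lambda - a^lambda}, times
#' the edge multipliers for the first and last groups. Counts are
#' integerized by largest-remainder rounding so they sum to \code{n} exactly.
#'
#' @param scheme a \code{sampling_scheme}.
#' @param breaks group boundary ages (default the scheme's breaks, else
#'   one-year groups).
#' @return data frame of class \code{age_group_plan} with columns
#'   \code{age_lo}, \code{age_hi}, \code{count}.
#' @examples
#' sch <- sampling_scheme(0.755, 0, 20, n = 10000)
#' nagegp(sch, breaks = 0:20)
#' @export
nagegp <- function(scheme, breaks = NULL) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (is.null(breaks)) breaks <- scheme$breaks
  if (is.null(breaks))
    breaks <- seq(scheme$age_min, scheme$age_max, by = 1)
  if (any(diff(breaks) <= 0) || length(breaks) < 2)
    stop("'breaks' must be strictly increasing", call. = FALSE)
  if (breaks[1] < scheme$age_min - 1e-8 ||
      breaks[length(breaks)] > scheme$age_max + 1e-8)
    stop("'breaks' must lie within the scheme's age range", call. = FALSE)
  w <- diff(breaks^scheme$lambda)
  w[1] <- w[1] * scheme$edge_low
  w[length(w)] <- w[length(w)] * scheme$edge_high
  counts <- largest_remainder(scheme$n * w / sum(w))
  structure(data.frame(age_lo = breaks[-length(breaks)], age_hi = breaks[-1],
                       count = counts),
            class = c("age_group_plan", "data.frame"))
}

# integerize keeping the total: floor, then distribute the shortfall to the
# largest fractional remainders
largest_remainder <- function(x) {
  f <- floor(x)
  short <- round(sum(x)) - sum(f)
  if (short > 0) {
    idx <- order(x - f, decreasing = TRUE)[seq_len(short)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

#' Draw ages for a grouped design
#'
#' Ages within each group are uniform random deviates within the group's age
#' range, with exactly the planned count per group.
#'
#' @param plan an \code{age_group_plan} from [nagegp()] or built by hand
#'   (columns \code{age_lo}, \code{age_hi}, \code{count}).
#' @return vector of \code{sum(plan$count)} ages.
#' @export
grouped_ages <- function(plan) {
  stopifnot(all(c("age_lo", "age_hi", "count") %in% names(plan)))
  unlist(lapply(seq_len(nrow(plan)), function(i) {
    stats::runif(plan$count[i], plan$age_lo[i], plan$age_hi[i])
  }), use.names = FALSE)
}

#' Age-group plan emulating the 1972 Cuban Growth Study layout
#'
#' An illustrative 27-group plan with 4-monthly groups in infancy widening to
#' yearly groups in childhood, and counts shaped like a growth-velocity curve
#' (infant and pubertal over-sampling). The published design's exact counts
#' are not reproduced; this is a documented synthetic stand-in with the same
#' group structure and qualitative shape.
#'
#' @param n total subjects (default 6878).
#' @return an \code{age_group_plan}.
#' @export
cuban_plan <- function(n = 6878) {
  breaks <- c(0, 1/3, 2/3, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10, 10.5, 11,
              11.5, 12, 12.5, 13, 13.5, 14, 14.5, 15.5, 16.5, 17.5, 18.5, 20)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # velocity-curve shape: high in infancy, trough mid-childhood, pubertal peak
  shape <- 2.5 * exp(-mid / 1.2) + 0.6 + 1.1 * exp(-((mid - 14) / 1.8)^2)
  w <- shape * diff(breaks)
  counts <- largest_remainder(n * w / sum(w))
  structure(data.frame(age_lo = breaks[-length(breaks)], age_hi = breaks[-1],
                       count = counts),
            class = c("age_group_plan", "data.frame"))
}

#' Simulate a cross-sectional dataset from a base model
#'
#' Draws measurement ages from the scheme (grouped if it has breaks,
#' otherwise by inverse-transform age^lambda sampling), then simulates one
#' measurement per age by drawing a uniform proportion, converting it to a
#' z-score and applying the BCCG centile transform at the base model's
#' moments for that age.
#'
#' @param model a \code{moment_curves} base model.
#' @param scheme a \code{sampling_scheme} whose age range lies inside the
#'   model domain.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first.
#' @return data frame with columns \code{age} and \code{y}.
#' @examples
#' d <- simulate_dataset(growth_fixture("height"),
#'                       sampling_scheme(0.5, 0, 20, n = 500), seed = 1)
#' head(d)
#' @export
simulate_dataset <- function(model, scheme, seed = NULL) {
  stopifnot(inherits(model, "moment_curves"),
            inherits(scheme, "sampling_scheme"))
  if (scheme$age_min < model$age_min - 1e-8 ||
      scheme$age_max > model$age_max + 1e-8)
    stop("sampling scheme age range outside the model domain", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ages <- if (is.null(scheme$breaks)) sample_ages(scheme)
          else grouped_ages(nagegp(scheme))
  m <- eval_moments(model, ages)
  data.frame(age = ages, y = rbccg(m$mu, m$sigma, m$nu))
}
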