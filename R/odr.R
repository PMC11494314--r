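# Weighted orthogonal distance regression for a straight line.
#
# Minimizes the effective-variance objective
#   S(a, b) = sum_i (y_i - a - b x_i)^2 / (sy_i^2 + b^2 sx_i^2),
# the maximum-likelihood line when both coordinates carry independent
# Gaussian errors with known standard deviations. With equal errors this
# reduces to classical orthogonal (total least squares) regression. The
# slope is parameterized by its angle so steep lines pose no problem;
# the intercept has a closed form given the slope.

#' Orthogonal distance regression slope
#'
#' Fits `y ~ a + b x` by weighted orthogonal distance regression with
#' per-point errors on both axes. The slope standard error is estimated
#' by the jackknife (leave-one-out).
#'
#' @param x,y numeric vectors of coordinates.
#' @param x_se,y_se per-point standard errors (recycled; default 1 on
#'   both axes, i.e. plain orthogonal regression).
#' @return a one-row tibble with columns `slope`, `intercept`,
#'   `slope_se`, `n`.
#' @export
odr_slope <- function(x, y, x_se = 1, y_se = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  x_se <- rep_len(x_se, n)
  y_se <- rep_len(y_se, n)
  stopifnot(all(x_se > 0), all(y_se > 0))
  fit <- odr_fit_angle(x, y, x_se, y_se)
  se <- NA_real_
  if (n >= 3) {
    loo <- vapply(seq_len(n), function(i) {
      odr_fit_angle(x[-i], y[-i], x_se[-i], y_se[-i])$slope
    }, numeric(1))
    loo <- loo[is.finite(loo)]
    m <- length(loo)
    if (m >= 2) se <- sqrt((m - 1) / m * sum((loo - mean(loo))^2))
  }
  tibble(slope = fit$slope, intercept = fit$intercept, slope_se = se,
         n = n)
}

odr_fit_angle <- function(x, y, x_se, y_se) {
  obj <- function(theta) {
    b <- tan(theta)
    w <- 1 / (y_se^2 + b^2 * x_se^2)
    a <- sum(w * (y - b * x)) / sum(w)
    sum(w * (y - a - b * x)^2)
  }
  # coarse scan over angles to avoid local minima, then refine
  grid <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = 181)
  vals <- vapply(grid, obj, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(obj, lower = lo, upper = hi, tol = 1e-12)
  b <- tan(opt$minimum)
  w <- 1 / (y_se^2 + b^2 * x_se^2)
  a <- sum(w * (y - b * x)) / sum(w)
  list(slope = b, intercept = a)
}
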