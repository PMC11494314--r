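# Coincidence probabilities and order-2 (collision) entropies.
#
# p_C[X] = sum_x P(x)^2 is the probability that two independent draws of
# the feature X agree (Simpson's index; 1/p_C is the effective number of
# distinct values). From a sample of distinct clones it is estimated
# without bias by the fraction of unordered clone pairs that coincide,
# sum_x n_x (n_x - 1) / (N (N - 1)). Conditional coincidence probabilities
# average per-group values with rho_2 weights, rho_2(y) =
# P(y)^2 / sum_y P(y)^2, which preserves the additivity
# H2[X,Y] = H2[X] + H2[Y|X] of collision entropy.

new_coincidence_estimate <- function(p_hat, coincident_pairs, total_pairs,
                                     n, se = NA_real_,
                                     group_weights = NULL) {
  structure(list(p_hat = p_hat,
                 coincident_pairs = coincident_pairs,
                 total_pairs = total_pairs,
                 n = n, se = se, group_weights = group_weights),
            class = "coincidence_estimate")
}

#' @export
print.coincidence_estimate <- function(x, ...) {
  cat("<coincidence_estimate> p_hat =", format(x$p_hat),
      sprintf("(%s / %s pairs, n = %d)", format(x$coincident_pairs),
              format(x$total_pairs), x$n), "\n")
  if (!is.na(x$se)) cat("  bootstrap se =", format(x$se), "\n")
  if (!is.null(x$group_weights)) {
    cat("  rho2 weights over", length(x$group_weights), "group(s)\n")
  }
  invisible(x)
}

#' Exact coincidence probability of a categorical distribution
#'
#' \eqn{p_C[X] = \sum_x P(x)^2}, the probability that two independent
#' draws agree; its reciprocal is the Simpson diversity (effective number
#' of distinct values).
#'
#' @param dist numeric vector of outcome probabilities (non-negative,
#'   summing to 1 within `tol`).
#' @param tol tolerance on the normalization check.
#' @return the coincidence probability, a number in (0, 1].
#' @export
pc_exact <- function(dist, tol = 1e-9) {
  stopifnot(is.numeric(dist), all(dist >= 0))
  if (abs(sum(dist) - 1) > tol) {
    stop("distribution does not sum to 1 (off by ",
         format(sum(dist) - 1), ")")
  }
  sum(dist^2)
}

#' Pair-counting estimate of the coincidence probability
#'
#' Unbiased estimator of \eqn{p_C[X]} from a sample of distinct clones:
#' the fraction of unordered clone pairs whose feature values coincide,
#' \eqn{\sum_x n_x (n_x - 1) / (N (N - 1))}. `NA` values are excluded
#' before counting. With fewer than two usable values the estimate is
#' returned with `total_pairs = 0` and `p_hat = NA`.
#'
#' @param values a feature column (character vector; `NA` = missing).
#' @param bootstrap number of clone-level bootstrap replicates used for
#'   the standard error (0 = no resampling, `se = NA`).
#' @param seed optional seed for the bootstrap.
#' @param weights optional positive clone weights (e.g. clone counts) for
#'   count-weighted estimation; the default counts each distinct clone
#'   once.
#' @return a `coincidence_estimate`.
#' @export
pc_pairs <- function(values, bootstrap = 0, seed = NULL, weights = NULL) {
  if (!is.null(weights)) {
    keep <- !is.na(values)
    values <- rep(values[keep], times = round(weights[keep]))
  }
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(new_coincidence_estimate(NA_real_, 0, 0, n))
  cnt <- as.numeric(table(values))
  coinc <- sum(cnt * (cnt - 1)) / 2
  total <- n * (n - 1) / 2
  se <- NA_real_
  if (bootstrap > 0) {
    reps <- with_seed(seed, vapply(seq_len(bootstrap), function(i) {
      v <- sample(values, n, replace = TRUE)
      cb <- as.numeric(table(v))
      sum(cb * (cb - 1)) / (n * (n - 1))
    }, numeric(1)))
    se <- stats::sd(reps)
  }
  new_coincidence_estimate(coinc / total, coinc, total, n, se = se)
}

# Resolve the group probabilities P(y) used to build rho2 weights.
# `weights`: "uniform", "size", or a named/positional numeric vector.
resolve_group_probs <- function(weights, group_names, group_sizes) {
  if (is.character(weights) && length(weights) == 1) {
    p <- switch(weights,
      uniform = rep(1, length(group_names)),
      size = as.numeric(group_sizes),
      stop("unknown weighting scheme: '", weights, "'"))
  } else if (is.numeric(weights)) {
    p <- if (!is.null(names(weights))) {
      if (!all(group_names %in% names(weights))) {
        stop("explicit weights missing group(s): ",
             paste(setdiff(group_names, names(weights)), collapse = ", "))
      }
      unname(weights[group_names])
    } else {
      if (length(weights) != length(group_names)) {
        stop("explicit weights have wrong length")
      }
      weights
    }
  } else stop("invalid weights")
  if (any(p < 0) || sum(p) <= 0) stop("weights must be non-negative")
  p / sum(p)
}

#' Conditional coincidence probability from grouped samples
#'
#' Estimates \eqn{p_C[X|Y] = \sum_y \rho_2(y)\, p_C[X|y]} with
#' \eqn{\rho_2(y) = P(y)^2 / \sum_y P(y)^2}. Each group's conditional
#' coincidence probability is the pair-counting estimate within that
#' group. Groups with fewer than two usable values are dropped (and the
#' group probabilities renormalized over the retained groups).
#'
#' @param values a feature column (character vector; `NA` = missing).
#' @param groups the conditioning labels, same length as `values`.
#' @param weights the group distribution P(y) feeding the rho2 weights:
#'   `"uniform"` (default), `"size"` (empirical group sizes), or an
#'   explicit numeric vector (named by group or positional in group sort
#'   order).
#' @return a `coincidence_estimate`; `group_weights` holds the rho2
#'   weights actually used.
#' @export
pc_conditional <- function(values, groups, weights = "uniform") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  sp <- split(values, groups)
  sizes <- lengths(sp)
  usable <- sizes >= 2
  if (!any(usable)) return(new_coincidence_estimate(NA_real_, 0, 0,
                                                    length(values)))
  sp <- sp[usable]
  est <- lapply(sp, pc_pairs)
  p_y <- resolve_group_probs(weights, names(sp), lengths(sp))
  rho2 <- p_y^2 / sum(p_y^2)
  p_hat <- sum(rho2 * vapply(est, `[[`, numeric(1), "p_hat"))
  new_coincidence_estimate(
    p_hat,
    sum(vapply(est, `[[`, numeric(1), "coincident_pairs")),
    sum(vapply(est, `[[`, numeric(1), "total_pairs")),
    length(values),
    group_weights = setNames(rho2, names(sp)))
}

#' Exact conditional coincidence probability
#'
#' Evaluates \eqn{p_C[X|Y] = \sum_y \rho_2(y)\, p_C[X|y]} on exact
#' conditional distributions.
#'
#' @param cond a list of conditional distributions P(x|y), one numeric
#'   probability vector per outcome y.
#' @param p_y the distribution P(y) over outcomes of Y (normalized
#'   internally).
#' @return the conditional coincidence probability.
#' @export
pc_conditional_exact <- function(cond, p_y) {
  stopifnot(is.list(cond), length(cond) == length(p_y), all(p_y >= 0))
  p_y <- p_y / sum(p_y)
  rho2 <- p_y^2 / sum(p_y^2)
  sum(rho2 * vapply(cond, pc_exact, numeric(1)))
}

#' Collision (order-2 Renyi) entropy from a coincidence probability
#'
#' \eqn{H_2[X] = -\log_2 p_C[X]}, in bits.
#'
#' @param pc coincidence probability/probabilities in (0, 1].
#' @return entropy in bits; `NA` (with a warning) where `pc` is zero or
#'   missing, since no coincidences means the entropy is unresolved by
#'   the sample.
#' @export
entropy2 <- function(pc) {
  bad <- is.na(pc) | pc <= 0
  if (any(bad)) {
    warning("coincidence probability of 0 or NA: entropy undefined; ",
            "estimation requires at least one coincidence")
  }
  out <- rep(NA_real_, length(pc))
  out[!bad] <- -log2(pc[!bad])
  out
}
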