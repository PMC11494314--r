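# Relevancy (coincidence mutual information), conditional relevancy and
# interaction information.
#
# Relevancy of a feature X for specificity Pi is
#   I2(X, Pi) = log2( p_C[X|Pi] / p_C[X] ),
# the log-ratio of the conditional coincidence probability among
# epitope-specific clones (rho2-weighted over epitope groups) to the
# background coincidence probability. Conditional relevancy conditions
# both terms on a second feature Y; interaction information is the excess
# of the combined-feature relevancy over the sum of the single-feature
# relevancies (positive = synergy, negative = redundancy).

information_score <- function(bits, feature, conditioning = NA_character_,
                              scope = "global", ci_low = NA_real_,
                              ci_high = NA_real_, n_specific = NA_integer_,
                              n_background = NA_integer_) {
  out <- tibble(feature = feature, conditioning = conditioning,
                scope = scope, bits = bits, ci_low = ci_low,
                ci_high = ci_high, n_specific = as.integer(n_specific),
                n_background = as.integer(n_background),
                units = "bits")
  class(out) <- c("information_score", class(out))
  out
}

# log2 ratio with NA/zero guarding; emits a diagnostic on failure.
log2_ratio <- function(p_num, p_den, what = "relevancy") {
  if (is.na(p_num) || is.na(p_den) || p_num <= 0 || p_den <= 0) {
    warning(what, " undefined: zero coincident pairs in a required ",
            "estimate (numerator p_C = ", format(p_num),
            ", denominator p_C = ", format(p_den), ")")
    return(NA_real_)
  }
  log2(p_num / p_den)
}

# Percentile bootstrap over clones, resampling the background and each
# epitope group independently. `bits_fun(idx_bg, idx_by_group)` recomputes
# the statistic from resampled row indices.
bootstrap_ci <- function(bits_fun, n_bg, group_idx, bootstrap, conf, seed) {
  reps <- with_seed(seed, vapply(seq_len(bootstrap), function(b) {
    ib <- sample.int(n_bg, n_bg, replace = TRUE)
    ig <- lapply(group_idx, function(ix) sample(ix, length(ix),
                                                replace = TRUE))
    suppressWarnings(bits_fun(ib, unlist(ig, use.names = FALSE)))
  }, numeric(1)))
  reps <- reps[is.finite(reps)]
  if (length(reps) < 2) return(c(NA_real_, NA_real_))
  alpha <- (1 - conf) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Feature relevancy: coincidence mutual information with specificity
#'
#' \eqn{I_2(X, \Pi) = \log_2 (p_C[X|\Pi] / p_C[X])}: how many bits a match
#' in feature X is worth for deciding epitope specificity. The conditional
#' coincidence probability averages per-epitope pair-counting estimates
#' with rho2 weights; the background term is the pair-counting estimate on
#' the background table.
#'
#' @param specific repertoire tibble of epitope-labeled clones (column
#'   `epitope` non-missing).
#' @param background repertoire tibble of background clones.
#' @param feature a mini-language string or [tcr_feature()].
#' @param weights epitope distribution P(pi) feeding the rho2 weights:
#'   `"uniform"` (default), `"size"`, or explicit numeric.
#' @param bootstrap number of bootstrap replicates for the confidence
#'   interval (0 = none). Clones are resampled within each epitope group
#'   and within the background independently.
#' @param conf confidence level for the bootstrap interval.
#' @param seed optional bootstrap seed.
#' @return a one-row `information_score` tibble (columns `feature`,
#'   `scope`, `bits`, `ci_low`, `ci_high`, `n_specific`, `n_background`).
#' @export
relevancy <- function(specific, background, feature, weights = "uniform",
                      bootstrap = 0, conf = 0.95, seed = NULL) {
  f <- tcr_feature(feature)
  xs <- extract_feature(specific, f)
  eps <- as.character(specific$epitope)
  xb <- extract_feature(background, f)
  bits_at <- function(ib, is) {
    pcb <- pc_pairs(xb[ib])$p_hat
    pcs <- pc_conditional(xs[is], eps[is], weights = weights)$p_hat
    log2(pcs / pcb)
  }
  pcb <- pc_pairs(xb)
  pcs <- pc_conditional(xs, eps, weights = weights)
  bits <- log2_ratio(pcs$p_hat, pcb$p_hat)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap > 0 && !is.na(bits)) {
    keep <- which(!is.na(xs) & !is.na(eps))
    ci <- bootstrap_ci(bits_at, length(xb), split(keep, eps[keep]),
                       bootstrap, conf, seed)
  }
  information_score(bits, f$name, scope = "global",
                    ci_low = ci[1], ci_high = ci[2],
                    n_specific = pcs$n, n_background = pcb$n)
}

#' Local relevancy for one epitope
#'
#' \eqn{i_2(X, \pi) = \log_2 (p_C[X|\pi] / p_C[X])}: the information gain
#' for a single epitope rather than the rho2 average over all epitopes.
#'
#' @inheritParams relevancy
#' @param epitope which epitope to restrict to; defaults to the single
#'   epitope present in `specific`.
#' @return a one-row `information_score` tibble with `scope =
#'   "local:<epitope>"`.
#' @export
local_relevancy <- function(specific, background, feature, epitope = NULL,
                            bootstrap = 0, conf = 0.95, seed = NULL) {
  eps <- unique(stats::na.omit(as.character(specific$epitope)))
  if (is.null(epitope)) {
    if (length(eps) != 1) {
      stop("specify `epitope`: table contains ", length(eps), " epitopes")
    }
    epitope <- eps
  }
  sub <- specific[!is.na(specific$epitope) & specific$epitope == epitope, ]
  out <- relevancy(sub, background, feature, weights = "uniform",
                   bootstrap = bootstrap, conf = conf, seed = seed)
  out$scope <- paste0("local:", epitope)
  out
}

#' Conditional relevancy: information remaining given a second feature
#'
#' \eqn{I_2(X, \Pi | Y) = H_2[X|Y] - H_2[X|\Pi, Y]}: the information
#' feature X still provides about specificity once feature Y is known.
#' Conditioning on \eqn{(\Pi, Y)} groups the specific clones by epitope
#' crossed with Y-value; the joint group probabilities are
#' \eqn{P(\pi) \hat P(y|\pi)} with \eqn{P(\pi)} taken from `weights` and
#' \eqn{\hat P(y|\pi)} the empirical within-epitope share, and feed the
#' rho2 weighting. The background term conditions on Y with empirical
#' (size) stratum probabilities.
#'
#' @inheritParams relevancy
#' @param given the conditioning feature Y (string or [tcr_feature()]).
#' @return a one-row `information_score` tibble with `conditioning` set.
#' @export
conditional_relevancy <- function(specific, background, feature, given,
                                  weights = "uniform") {
  fx <- tcr_feature(feature)
  fy <- tcr_feature(given)
  xb <- extract_feature(background, fx)
  yb <- extract_feature(background, fy)
  pc_bg <- pc_conditional(xb, yb, weights = "size")
  xs <- extract_feature(specific, fx)
  ys <- extract_feature(specific, fy)
  eps <- as.character(specific$epitope)
  keep <- !is.na(xs) & !is.na(ys) & !is.na(eps)
  xs <- xs[keep]; ys <- ys[keep]; eps <- eps[keep]
  ep_names <- sort(unique(eps))
  p_pi <- resolve_group_probs(weights, ep_names,
                              as.numeric(table(eps)[ep_names]))
  joint <- paste(eps, ys, sep = FEATURE_SEP)
  # P(pi, y) = P(pi) * empirical P(y | pi)
  jn <- sort(unique(joint))
  parts <- strsplit(jn, FEATURE_SEP, fixed = TRUE)
  j_ep <- vapply(parts, `[[`, character(1), 1)
  n_joint <- as.numeric(table(joint)[jn])
  n_ep <- as.numeric(table(eps)[j_ep])
  w_joint <- setNames(p_pi[match(j_ep, ep_names)] * n_joint / n_ep, jn)
  pc_spec <- pc_conditional(xs, joint, weights = w_joint)
  bits <- log2_ratio(pc_spec$p_hat, pc_bg$p_hat, "conditional relevancy")
  information_score(bits, fx$name, conditioning = fy$name,
                    scope = "global",
                    n_specific = pc_spec$n, n_background = pc_bg$n)
}

#' Interaction information between two features
#'
#' \eqn{I_{2,int}(X, Y | \Pi) = I_2([X,Y], \Pi) - I_2(X, \Pi) -
#' I_2(Y, \Pi)}: how much more (synergy, positive) or less (redundancy,
#' negative) the combined feature tells about specificity than the two
#' features separately. All three relevancies are computed on the shared
#' record subset where both features are non-missing, so the comparison is
#' like-for-like.
#'
#' @inheritParams relevancy
#' @param feature_x,feature_y the two features.
#' @param local optional epitope label: compute the local variant
#'   \eqn{i_{2,int}(X, Y | \pi)} for that epitope only.
#' @return a one-row `information_score` tibble; `feature` is the product
#'   feature name.
#' @export
interaction_information <- function(specific, background, feature_x,
                                    feature_y, weights = "uniform",
                                    local = NULL) {
  fx <- tcr_feature(feature_x)
  fy <- tcr_feature(feature_y)
  if (!is.null(local)) {
    specific <- specific[!is.na(specific$epitope) &
                           specific$epitope == local, ]
  }
  xs <- extract_feature(specific, fx)
  ys <- extract_feature(specific, fy)
  xb <- extract_feature(background, fx)
  yb <- extract_feature(background, fy)
  ks <- !is.na(xs) & !is.na(ys)
  kb <- !is.na(xb) & !is.na(yb)
  eps <- as.character(specific$epitope)[ks]
  xs <- xs[ks]; ys <- ys[ks]; xb <- xb[kb]; yb <- yb[kb]
  xys <- paste(xs, ys, sep = FEATURE_SEP)
  xyb <- paste(xb, yb, sep = FEATURE_SEP)
  i2 <- function(sv, bv) {
    log2_ratio(pc_conditional(sv, eps, weights = weights)$p_hat,
               pc_pairs(bv)$p_hat, "interaction information")
  }
  bits <- i2(xys, xyb) - i2(xs, xb) - i2(ys, yb)
  information_score(bits, paste0(fx$name, "+", fy$name),
                    scope = if (is.null(local)) "global"
                            else paste0("local:", local),
                    n_specific = length(xs), n_background = length(xb))
}

#' Pairwise relevancy grid
#'
#' Square grid of relevancies: the diagonal holds single-feature
#' relevancies, the off-diagonal the relevancy of the pairwise product
#' features. The companion [interaction_matrix()] subtracts the diagonal
#' sums from the off-diagonals to display synergy/redundancy.
#'
#' @inheritParams relevancy
#' @param features character vector of feature mini-language strings.
#' @return a symmetric numeric matrix of bits with the features as
#'   dimnames, class `relevancy_matrix`.
#' @export
relevancy_matrix <- function(specific, background, features,
                             weights = "uniform") {
  k <- length(features)
  m <- matrix(NA_real_, k, k, dimnames = list(features, features))
  for (i in seq_len(k)) {
    for (j in i:k) {
      spec <- if (i == j) features[i]
              else paste(features[i], features[j], sep = "+")
      m[i, j] <- m[j, i] <- relevancy(specific, background, spec,
                                      weights = weights)$bits
    }
  }
  structure(m, class = c("relevancy_matrix", "matrix", "array"))
}

#' Interaction grid derived from a relevancy grid
#'
#' Off-diagonal entries are the interaction information (off-diagonal
#' relevancy minus the sum of the two diagonal relevancies); the diagonal
#' is zero by construction.
#'
#' @param rm a [relevancy_matrix()].
#' @return a symmetric numeric matrix of bits.
#' @export
interaction_matrix <- function(rm) {
  d <- diag(rm)
  out <- unclass(rm) - outer(d, d, `+`)
  diag(out) <- 0
  out
}

# ---- exact-distribution evaluation -----------------------------------

#' Exact relevancy from enumerated distributions
#'
#' Evaluates \eqn{I_2(X,\Pi)} on exact categorical distributions: a list
#' of per-epitope conditional distributions, an epitope distribution, and
#' the background distribution.
#'
#' @param cond list of per-epitope distributions P(x|pi) (numeric
#'   probability vectors), or a single vector for one epitope.
#' @param p_epitope distribution over epitopes (defaults to uniform).
#' @param background background distribution P(x).
#' @return relevancy in bits.
#' @export
relevancy_exact <- function(cond, background, p_epitope = NULL) {
  if (is.numeric(cond)) cond <- list(cond)
  if (is.null(p_epitope)) p_epitope <- rep(1 / length(cond), length(cond))
  log2(pc_conditional_exact(cond, p_epitope) / pc_exact(background))
}

# Internal: pc[X|Y] from a joint matrix P(x, y) (x rows, y cols).
pc_cond_from_joint <- function(m) {
  p_y <- colSums(m)
  use <- p_y > 0
  cond <- lapply(which(use), function(j) m[, j] / p_y[j])
  pc_conditional_exact(cond, p_y[use])
}

#' Exact conditional relevancy from enumerated joint distributions
#'
#' Evaluates \eqn{I_2(X, \Pi | Y) = H_2[X|Y] - H_2[X|\Pi,Y]} on exact
#' joint distributions of (X, Y).
#'
#' @param background_joint matrix of background P(x, y) (x rows, y cols).
#' @param specific_joints list of per-epitope joint matrices P(x, y|pi).
#' @param p_epitope distribution over epitopes (defaults to uniform).
#' @return conditional relevancy in bits.
#' @export
conditional_relevancy_exact <- function(background_joint, specific_joints,
                                        p_epitope = NULL) {
  if (is.matrix(specific_joints)) specific_joints <- list(specific_joints)
  k <- length(specific_joints)
  if (is.null(p_epitope)) p_epitope <- rep(1 / k, k)
  # joint groups (pi, y): prob p_pi * P(y|pi), conditional P(x|pi,y)
  cond <- list(); w <- numeric(0)
  for (i in seq_len(k)) {
    m <- specific_joints[[i]]
    p_y <- colSums(m)
    for (j in which(p_y > 0)) {
      cond <- c(cond, list(m[, j] / p_y[j]))
      w <- c(w, p_epitope[i] * p_y[j])
    }
  }
  log2(pc_conditional_exact(cond, w) / pc_cond_from_joint(background_joint))
}

#' Exact interaction information from enumerated joint distributions
#'
#' Evaluates \eqn{I_2([X,Y],\Pi) - I_2(X,\Pi) - I_2(Y,\Pi)} on exact joint
#' distributions of (X, Y) for the background and each epitope.
#'
#' @inheritParams conditional_relevancy_exact
#' @return interaction information in bits (negative = redundancy).
#' @export
interaction_exact <- function(background_joint, specific_joints,
                              p_epitope = NULL) {
  if (is.matrix(specific_joints)) specific_joints <- list(specific_joints)
  k <- length(specific_joints)
  if (is.null(p_epitope)) p_epitope <- rep(1 / k, k)
  i2 <- function(take) {
    relevancy_exact(lapply(specific_joints, take), take(background_joint),
                    p_epitope)
  }
  i2(function(m) as.vector(m)) - i2(rowSums) - i2(colSums)
}
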