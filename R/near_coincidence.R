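# Near-coincidences: distance-resolved coincidence probabilities and
# fuzzy-match mutual information.
#
# For a feature X with a distance metric d, p_C[X](Delta) is the
# probability that two independent draws are at distance exactly Delta
# (Eq.-18-style Kronecker binning; a cumulative <= Delta option is
# provided but non-default). The pair-counting analogue is the fraction
# of unordered distinct-clone pairs at that distance. Near-coincidence
# mutual information at Delta is log2 of the specific-to-background ratio
# of these probabilities, and feeds the same posterior-odds calculus as
# exact matches.

DISTANCE_METRICS <- c("levenshtein_cdr3b", "levenshtein_cdr3a",
                      "levenshtein_sum")

metric_columns <- function(metric) {
  switch(metric,
    levenshtein_cdr3a = "cdr3_alpha",
    levenshtein_cdr3b = "cdr3_beta",
    levenshtein_sum = c("cdr3_alpha", "cdr3_beta"),
    stop("unknown metric: '", metric, "'"))
}

#' Levenshtein edit distance
#'
#' Minimum number of insertions, deletions and substitutions required to
#' turn one sequence into another (unit costs). Vectorized elementwise
#' over pairs.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(mapply(function(x, y) adist(x, y)[1, 1], a, b,
                    USE.NAMES = FALSE))
}

# All-pairs distance histogram over distinct clones. `tab` is a
# repertoire table; `cols` the CDR3 column(s) defining the metric (two
# columns = summed per-chain edit distance). Records missing any needed
# column are excluded. Returns pair counts per distance: same-value pairs
# contribute at Delta = 0; unordered cross pairs at their distance.
pair_distance_counts <- function(tab, cols) {
  s <- lapply(cols, function(cl) as.character(tab[[cl]]))
  keep <- !Reduce(`|`, lapply(s, is.na))
  s <- lapply(s, `[`, keep)
  n <- sum(keep)
  if (n < 2) {
    return(list(delta = integer(0), pairs = numeric(0), total = 0, n = n))
  }
  key <- do.call(paste, c(s, sep = FEATURE_SEP))
  tt <- table(key)
  keys <- names(tt)
  cnt <- as.numeric(tt)
  parts <- strsplit(keys, FEATURE_SEP, fixed = TRUE)
  m <- length(keys)
  D <- matrix(0L, m, m)
  for (i in seq_along(cols)) {
    u <- vapply(parts, `[[`, character(1), i)
    D <- D + adist(u)
  }
  iu <- upper.tri(D)
  d_all <- c(D[iu], rep(0L, m))
  w_all <- c(outer(cnt, cnt)[iu], cnt * (cnt - 1) / 2)
  agg <- rowsum(w_all, group = d_all)
  delta <- as.integer(rownames(agg))
  ord <- order(delta)
  list(delta = delta[ord], pairs = as.numeric(agg[ord, 1]),
       total = n * (n - 1) / 2, n = n)
}

# Per-distance probabilities on a contiguous 0..dmax grid.
counts_to_probs <- function(pd, dmax) {
  p <- numeric(dmax + 1)
  sel <- pd$delta <= dmax
  p[pd$delta[sel] + 1] <- pd$pairs[sel] / pd$total
  p
}

#' Pair-counting coincidence probability at a distance
#'
#' Fraction of unordered distinct-clone pairs whose feature values are at
#' exactly distance `delta` (pairs of identical values count at distance
#' 0; within-clone self-pairs are excluded). Over all distances these
#' fractions partition the pairs and sum to 1.
#'
#' @param values character vector of sequences, or a data frame / list of
#'   two character vectors for a summed two-chain metric.
#' @param delta non-negative integer distance.
#' @return a `coincidence_estimate` for the chosen distance class.
#' @export
pc_at_distance <- function(values, delta) {
  vl <- if (is.data.frame(values)) as.list(values)
        else if (is.list(values)) values
        else list(values)
  vl <- lapply(vl, as.character)
  names(vl) <- paste0("c", seq_along(vl))
  tab <- as.data.frame(vl, stringsAsFactors = FALSE)
  pd <- pair_distance_counts(tab, names(tab))
  if (pd$total == 0) return(new_coincidence_estimate(NA_real_, 0, 0, pd$n))
  hit <- pd$pairs[match(delta, pd$delta)]
  if (is.na(hit)) hit <- 0
  new_coincidence_estimate(hit / pd$total, hit, pd$total, pd$n)
}

#' Exact coincidence probability at a distance
#'
#' \eqn{p_C[X](\Delta) = \sum_{x,x'} P(x) P(x')\,
#' \delta_{d(x,x'),\Delta}} evaluated on an exact distribution and a
#' precomputed distance matrix.
#'
#' @param dist numeric probability vector over outcomes.
#' @param D integer distance matrix between the outcomes (same order).
#' @param delta non-negative integer distance.
#' @return the probability that two independent draws are at distance
#'   `delta`.
#' @export
pc_at_distance_exact <- function(dist, D, delta) {
  stopifnot(nrow(D) == length(dist), ncol(D) == length(dist))
  sum(outer(dist, dist)[D == delta])
}

#' Distance-resolved coincidence profile
#'
#' Computes, for every distance 0..`delta_max`, the background and
#' specific (rho2-weighted over epitopes) pair-counting coincidence
#' probabilities and the near-coincidence mutual information
#' \eqn{I_2^\Delta = \log_2(p_C[X|\Pi](\Delta) / p_C[X](\Delta))}.
#'
#' @param specific repertoire tibble of epitope-labeled clones.
#' @param background repertoire tibble of background clones.
#' @param metric `"levenshtein_cdr3b"`, `"levenshtein_cdr3a"`, or
#'   `"levenshtein_sum"` (summed per-chain edit distance; records missing
#'   either chain excluded).
#' @param delta_max largest distance to report (default: largest distance
#'   observed in either population).
#' @param weights epitope distribution for the rho2 weighting
#'   (`"uniform"`, `"size"`, or explicit numeric).
#' @param cumulative if `TRUE`, report cumulative (`<= delta`) rather
#'   than exact-distance probabilities.
#' @return a tibble of class `distance_profile` with columns `delta`,
#'   `pc_bg`, `pc_spec`, `mi_bits` (NA where either probability is 0);
#'   attribute `metric`.
#' @export
distance_profile <- function(specific, background,
                             metric = "levenshtein_cdr3b",
                             delta_max = NULL, weights = "uniform",
                             cumulative = FALSE) {
  metric <- match.arg(metric, DISTANCE_METRICS)
  cols <- metric_columns(metric)
  pd_bg <- pair_distance_counts(background, cols)
  eps <- as.character(specific$epitope)
  groups <- split(seq_len(nrow(specific)), eps)
  pd_sp <- lapply(groups, function(ix)
    pair_distance_counts(specific[ix, , drop = FALSE], cols))
  pd_sp <- pd_sp[vapply(pd_sp, function(p) p$total > 0, logical(1))]
  if (pd_bg$total == 0 || length(pd_sp) == 0) {
    stop("need at least two usable records in background and in at ",
         "least one epitope group")
  }
  dmax_obs <- max(c(pd_bg$delta,
                    unlist(lapply(pd_sp, `[[`, "delta"))), 0)
  dmax <- if (is.null(delta_max)) dmax_obs else min(delta_max, dmax_obs)
  p_bg <- counts_to_probs(pd_bg, dmax)
  p_y <- resolve_group_probs(weights, names(pd_sp),
                             vapply(pd_sp, `[[`, numeric(1), "n"))
  rho2 <- p_y^2 / sum(p_y^2)
  p_sp <- Reduce(`+`, Map(function(p, w) w * counts_to_probs(p, dmax),
                          pd_sp, rho2))
  if (cumulative) {
    p_bg <- cumsum(p_bg)
    p_sp <- cumsum(p_sp)
  }
  mi <- ifelse(p_bg > 0 & p_sp > 0, log2(p_sp / p_bg), NA_real_)
  out <- tibble(delta = 0:dmax, pc_bg = p_bg, pc_spec = p_sp,
                mi_bits = mi)
  attr(out, "metric") <- metric
  attr(out, "cumulative") <- cumulative
  class(out) <- c("distance_profile", class(out))
  out
}

#' Near-coincidence mutual information at one distance
#'
#' The information a fuzzy match at distance `delta` provides about
#' specificity: \eqn{\log_2(p_C[X|\Pi](\Delta) / p_C[X](\Delta))}. At
#' `delta = 0` this reduces to the exact-match relevancy of the feature.
#'
#' @inheritParams distance_profile
#' @param delta non-negative integer distance.
#' @return a one-row `information_score` tibble; `bits` is `NA` (with a
#'   diagnostic) when either population has no pairs at `delta`.
#' @export
near_mi <- function(specific, background, metric = "levenshtein_cdr3b",
                    delta = 0, weights = "uniform") {
  prof <- distance_profile(specific, background, metric = metric,
                           delta_max = delta, weights = weights)
  row <- prof[prof$delta == delta, ]
  bits <- if (nrow(row) == 0) NA_real_ else row$mi_bits
  if (is.na(bits)) {
    warning("near-coincidence MI undefined at delta = ", delta,
            ": zero pairs in one of the populations")
  }
  information_score(bits, metric, scope = paste0("delta=", delta))
}
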