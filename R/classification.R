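# Converting bits into Bayesian classification odds and minimal priors.
#
# Matching a query receptor to an annotated reference in a feature worth
# I2 bits multiplies the prior odds of specificity by 2^I2
# (O_post = 2^I2 O_prior). Requiring the posterior odds to reach a
# threshold T therefore demands a minimal prior probability
# P_prior >= T 2^-I2 / (1 + T 2^-I2).

#' Convert probability to odds and back
#'
#' @param p probability in (0, 1).
#' @param o positive odds.
#' @return `prob_to_odds` returns `p / (1 - p)`; `odds_to_prob` returns
#'   `o / (1 + o)`. Exact inverses of each other.
#' @export
prob_to_odds <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  p / (1 - p)
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(o) {
  stopifnot(all(o > 0))
  o / (1 + o)
}

#' Posterior odds after a feature match
#'
#' \eqn{O_{post} = 2^{bits} \times O_{prior}}: each bit of coincidence
#' mutual information doubles the posterior odds of correct
#' classification.
#'
#' @param prior_odds positive prior odds.
#' @param bits information carried by the match, in bits.
#' @return posterior odds.
#' @export
posterior_odds <- function(prior_odds, bits) {
  stopifnot(all(prior_odds > 0))
  2^bits * prior_odds
}

#' Minimal prior probability for confident classification
#'
#' The smallest prior probability of specificity for which a match worth
#' `bits` bits pushes the posterior odds to at least `T`:
#' \eqn{P_{prior} = T 2^{-bits} / (1 + T 2^{-bits})}. Strictly decreasing
#' in `bits`, strictly increasing in `T`.
#'
#' @param bits information available from the match.
#' @param T required posterior odds (e.g. 19 for 95% posterior
#'   probability); alternatively supply `posterior`.
#' @param posterior required posterior probability, converted to odds.
#' @return minimal prior probability in (0, 1).
#' @export
min_prior <- function(bits, T = NULL, posterior = NULL) {
  if (is.null(T)) {
    if (is.null(posterior)) stop("supply `T` (odds) or `posterior`")
    T <- prob_to_odds(posterior)
  }
  stopifnot(all(T > 0))
  q <- T * 2^(-bits)
  q / (1 + q)
}

#' Critical prior probabilities along a distance profile
#'
#' Applies [min_prior()] to the near-coincidence mutual information at
#' every distance of a [distance_profile()], giving the prior fraction of
#' specific sequences needed for confident classification from a fuzzy
#' match at each distance.
#'
#' @param profile a [distance_profile()] (or any data frame with columns
#'   `delta` and `mi_bits`).
#' @param T required posterior odds; alternatively `posterior`.
#' @param posterior required posterior probability (default 0.95 when
#'   neither is given).
#' @return a tibble with columns `delta`, `mi_bits`, `min_prior`.
#' @export
critical_prior_curve <- function(profile, T = NULL, posterior = NULL) {
  if (is.null(T) && is.null(posterior)) posterior <- 0.95
  tibble(delta = profile$delta,
         mi_bits = profile$mi_bits,
         min_prior = min_prior(profile$mi_bits, T = T,
                               posterior = posterior))
}

#' Critical distance for reliable fuzzy-match classification
#'
#' The largest distance at which a fuzzy match still reaches the required
#' posterior odds given the prior: the largest `delta` with
#' \eqn{2^{MI(\Delta)} O_{prior} \ge T}. Beyond it, classification from a
#' match at that distance is unreliable.
#'
#' @inheritParams critical_prior_curve
#' @param prior_probability prior probability that a query is specific.
#' @return the critical distance (integer), or `NA` if no distance
#'   qualifies.
#' @export
critical_distance <- function(profile, prior_probability, T = NULL,
                              posterior = NULL) {
  if (is.null(T) && is.null(posterior)) posterior <- 0.95
  if (is.null(T)) T <- prob_to_odds(posterior)
  o_prior <- prob_to_odds(prior_probability)
  mi <- profile$mi_bits
  ok <- !is.na(mi) & posterior_odds(o_prior, mi) >= T
  if (!any(ok)) return(NA_integer_)
  as.integer(max(profile$delta[ok]))
}
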