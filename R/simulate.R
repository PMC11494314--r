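# Synthetic repertoires with the statistical structure the framework
# assumes.
#
# The background generator emulates draws from a V(D)J-recombination-like
# distribution: independent categorical V/J gene usage per chain, a
# categorical CDR3 length distribution, and i.i.d. amino acids within the
# CDR3 (leading cysteine fixed by convention). Alpha and beta chains are
# paired at random. Epitope-specific repertoires are mixtures of "binding
# modes": each mode anchors one V and J gene per chain and a CDR3 motif
# template reproduced with a per-position substitution rate; an optional
# false-positive fraction is drawn from the background instead. Because
# the generator's feature distribution is known in closed form, exact
# background coincidence probabilities are available via
# pc_background_exact(), mirroring the use of a generative model for the
# background distribution in real analyses.

# Skewed categorical gene usage: p_i proportional to exp(-decay * i).
gene_usage <- function(prefix, n, decay = 0.15) {
  p <- exp(-decay * (seq_len(n) - 1))
  setNames(p / sum(p), paste0(prefix, seq_len(n)))
}

default_length_dist <- function() {
  lens <- 10:18
  p <- exp(-0.5 * ((lens - 14) / 1.8)^2)
  setNames(p / sum(p), lens)
}

# CDR3-like amino acid composition: glycine/serine-rich, tryptophan and
# cysteine rare, a plausible stand-in for junctional sequence statistics.
default_aa_freq <- function() {
  w <- c(A = 6, C = 1, D = 4, E = 5, F = 3, G = 10, H = 2, I = 3, K = 3,
         L = 6, M = 1, N = 4, P = 4, Q = 5, R = 5, S = 10, T = 6, V = 5,
         W = 1, Y = 5)
  w[AA_LETTERS] / sum(w)
}

check_dist <- function(p, what) {
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(what, " must be a named probability vector summing to 1")
  }
  p
}

#' Configuration of the synthetic background repertoire
#'
#' Defines the background distribution: per-chain categorical V/J usage
#' (default: 20 V and 12 J genes per chain with exponentially decaying
#' usage), a categorical CDR3 length distribution (default: discretized
#' Gaussian over 10..18, mean 14), and an i.i.d. amino acid distribution
#' within the CDR3 (default: a glycine/serine-rich CDR3-like
#' composition). CDR3s start with the conserved cysteine when `lead_cys`
#' is `TRUE`.
#'
#' @param n_clones number of clones generated by default.
#' @param seed root seed; all generator randomness derives from it.
#' @param v_alpha,j_alpha,v_beta,j_beta named probability vectors of gene
#'   usage.
#' @param cdr3_length named probability vector over CDR3 lengths (names
#'   are integer lengths; shared by both chains).
#' @param aa_freq named probability vector over the 20 amino acids.
#' @param lead_cys logical; fix the first CDR3 residue to C.
#' @return a `background_config` list.
#' @export
background_config <- function(n_clones = 1000, seed = 1,
                              v_alpha = gene_usage("TRAV", 20),
                              j_alpha = gene_usage("TRAJ", 12),
                              v_beta = gene_usage("TRBV", 20),
                              j_beta = gene_usage("TRBJ", 12),
                              cdr3_length = default_length_dist(),
                              aa_freq = default_aa_freq(),
                              lead_cys = TRUE) {
  structure(list(
    n_clones = n_clones, seed = seed,
    v_alpha = check_dist(v_alpha, "v_alpha"),
    j_alpha = check_dist(j_alpha, "j_alpha"),
    v_beta = check_dist(v_beta, "v_beta"),
    j_beta = check_dist(j_beta, "j_beta"),
    cdr3_length = check_dist(cdr3_length, "cdr3_length"),
    aa_freq = check_dist(aa_freq[AA_LETTERS], "aa_freq"),
    lead_cys = lead_cys
  ), class = "background_config")
}

# n random CDR3s under the config's length/aa distributions (assumes an
# active RNG stream).
random_cdr3 <- function(n, config) {
  if (n == 0) return(character(0))
  lens <- as.integer(sample(names(config$cdr3_length), n, replace = TRUE,
                            prob = config$cdr3_length))
  body <- lens - as.integer(config$lead_cys)
  letters <- sample(AA_LETTERS, sum(body), replace = TRUE,
                    prob = config$aa_freq)
  f <- factor(rep.int(seq_len(n), body), levels = seq_len(n))
  out <- vapply(split(letters, f), paste, character(1), collapse = "")
  if (config$lead_cys) out <- paste0("C", out)
  unname(out)
}

# Sample full background records (assumes an active RNG stream).
sample_background_rows <- function(n, config, id_prefix = "bg") {
  draw <- function(p) if (n == 0) character(0)
                      else sample(names(p), n, replace = TRUE, prob = p)
  tibble(
    clone_id = if (n == 0) character(0) else sprintf("%s%06d", id_prefix,
                                                     seq_len(n)),
    v_alpha = draw(config$v_alpha), j_alpha = draw(config$j_alpha),
    cdr3_alpha = random_cdr3(n, config),
    v_beta = draw(config$v_beta), j_beta = draw(config$j_beta),
    cdr3_beta = random_cdr3(n, config),
    epitope = rep(NA_character_, n),
    clone_count = rep(1L, n)
  )
}

#' Generate a synthetic background repertoire
#'
#' Draws `config$n_clones` background clones; alpha and beta chains are
#' sampled independently (random pairing). Pure function of the seed:
#' the same config yields the identical table.
#'
#' @param config a [background_config()].
#' @return a repertoire tibble with `epitope = NA`.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "background_config"))
  out <- with_seed(child_seed(config$seed, 1),
                   sample_background_rows(config$n_clones, config))
  new_repertoire(out, list(source = "simulated_background",
                           n_input = config$n_clones, n_dropped = 0,
                           n_retained = config$n_clones))
}

#' Exact background coincidence probability of a feature
#'
#' Evaluates \eqn{p_C[X]} in closed form under the generative background
#' distribution: gene features from the usage vectors; CDR3 coincidence
#' as \eqn{\sum_L P(L)^2 q^{L - c}} with \eqn{q = \sum_a f_a^2} the
#' per-position collision probability (c = 1 when the leading cysteine is
#' fixed); length features from the length distribution; net charge by
#' convolving the per-residue charge distribution; remapped CDR3s with
#' the group-level collision probability. Product features multiply
#' component probabilities, exploiting the independence of loci in the
#' generator (do not use for products that repeat a locus).
#'
#' @param config a [background_config()].
#' @param feature a mini-language string or [tcr_feature()].
#' @return the exact coincidence probability.
#' @export
pc_background_exact <- function(config, feature) {
  f <- tcr_feature(feature)
  prod(vapply(f$leaves, function(leaf) leaf_pc_exact(config, leaf),
              numeric(1)))
}

leaf_pc_exact <- function(config, leaf) {
  usage <- switch(leaf$col,
    v_alpha = config$v_alpha, j_alpha = config$j_alpha,
    v_beta = config$v_beta, j_beta = config$j_beta, NULL)
  lead <- as.integer(config$lead_cys)
  p_len <- config$cdr3_length
  lens <- as.integer(names(p_len))
  switch(leaf$kind,
    gene = sum(usage^2),
    cdr3 = {
      q <- sum(config$aa_freq^2)
      sum(p_len^2 * q^(lens - lead))
    },
    length = sum(p_len^2),
    remap = {
      grp <- tapply(config$aa_freq, unname(leaf$map[AA_LETTERS]), sum)
      q <- sum(grp^2)
      sum(p_len^2 * q^(lens - lead))
    },
    charge = {
      hw <- leaf$h_weight %||% 0
      pc_charge_exact(config$aa_freq, p_len, lens - lead, hw)
    },
    stop("exact background coincidence not available for feature kind '",
         leaf$kind, "'")
  )
}

# Coincidence probability of the net charge under i.i.d. residues:
# convolve the per-residue charge distribution length by length, mix over
# lengths, then sum of squares. Integer h_weight only.
pc_charge_exact <- function(aa_freq, p_len, body_lens, h_weight = 0) {
  if (h_weight %% 1 != 0) {
    stop("exact charge coincidence requires an integer histidine weight")
  }
  per <- c(pos = sum(aa_freq[c("K", "R")]),
           neg = sum(aa_freq[c("D", "E")]),
           h = aa_freq[["H"]])
  # support -L..L per residue -> track offsets
  step_vals <- c(1, -1, h_weight, 0)
  step_p <- c(per[["pos"]], per[["neg"]], per[["h"]],
              1 - sum(per[c("pos", "neg")]) - per[["h"]])
  # collapse duplicate charge values (h_weight may be 0, 1 or -1)
  step <- tapply(step_p, step_vals, sum)
  sv <- as.integer(names(step))
  mix <- numeric(0)  # named by charge value
  add_into <- function(acc, vals, p) {
    for (i in seq_along(vals)) {
      key <- as.character(vals[i])
      acc[key] <- (if (key %in% names(acc)) acc[[key]] else 0) + p[i]
    }
    acc
  }
  for (k in seq_along(body_lens)) {
    L <- body_lens[k]
    # distribution of the sum of L i.i.d. steps
    d <- c(`0` = 1)
    for (r in seq_len(L)) {
      nd <- numeric(0)
      for (key in names(d)) {
        nd <- add_into(nd, as.integer(key) + sv, d[[key]] * step)
      }
      d <- nd
    }
    mix <- add_into(mix, as.integer(names(d)), p_len[k] * unname(d))
  }
  sum(mix^2)
}

#' Configuration of a mixture-of-modes epitope-specific repertoire
#'
#' An epitope-specific repertoire is modelled as a mixture of binding
#' modes. Each mode anchors one V and J gene per chain and a CDR3 motif
#' template per chain; clones drawn from the mode reproduce the template
#' with an independent per-position substitution probability
#' `noise_rate` (substitutes drawn from the background amino acid
#' distribution; the leading cysteine is never mutated). With probability
#' `false_positive_fraction` a clone is instead drawn from the
#' background.
#'
#' @param modes a list of modes; each mode is a list with elements
#'   `v_alpha`, `j_alpha`, `v_beta`, `j_beta`, `motif_alpha`,
#'   `motif_beta`. See [make_disjoint_modes()].
#' @param mode_weights mixture weights over modes (default uniform).
#' @param noise_rate per-position substitution probability in (0, 1).
#' @param false_positive_fraction fraction of clones drawn from the
#'   background, in [0, 1].
#' @param n_clones number of clones to generate.
#' @param epitope epitope label assigned to the generated clones.
#' @param seed generator seed.
#' @return a `mixture_config` list.
#' @export
mixture_config <- function(modes, mode_weights = NULL, noise_rate = 0.1,
                           false_positive_fraction = 0, n_clones = 2000,
                           epitope = "epitope1", seed = 2) {
  stopifnot(length(modes) >= 1, noise_rate >= 0, noise_rate < 1,
            false_positive_fraction >= 0, false_positive_fraction <= 1)
  needed <- c("v_alpha", "j_alpha", "v_beta", "j_beta",
              "motif_alpha", "motif_beta")
  for (m in modes) {
    if (!all(needed %in% names(m))) {
      stop("each mode needs fields: ", paste(needed, collapse = ", "))
    }
  }
  if (is.null(mode_weights)) {
    mode_weights <- rep(1 / length(modes), length(modes))
  }
  stopifnot(length(mode_weights) == length(modes))
  structure(list(modes = modes,
                 mode_weights = mode_weights / sum(mode_weights),
                 noise_rate = noise_rate,
                 false_positive_fraction = false_positive_fraction,
                 n_clones = n_clones, epitope = epitope, seed = seed),
            class = "mixture_config")
}

#' Build M disjoint binding modes
#'
#' Anchors a distinct V gene per chain for every mode (guaranteeing that
#' mode feature sets are disjoint for chain-level features) and draws a
#' random CDR3 motif template of fixed length per chain under the
#' background amino acid distribution. J genes cycle through the
#' available genes.
#'
#' @param M number of modes (at most the number of V genes in the
#'   background).
#' @param background a [background_config()].
#' @param motif_length CDR3 template length used for every mode (equal
#'   lengths keep within-mode coincidence comparable across modes).
#' @param seed seed for the motif draws.
#' @return a list of M mode lists suitable for [mixture_config()].
#' @export
make_disjoint_modes <- function(M, background, motif_length = 12,
                                seed = 3) {
  va <- names(background$v_alpha)
  vb <- names(background$v_beta)
  ja <- names(background$j_alpha)
  jb <- names(background$j_beta)
  stopifnot(M >= 1, M <= length(va), M <= length(vb))
  cfg_fixed_len <- background
  cfg_fixed_len$cdr3_length <- setNames(1, motif_length)
  motifs <- with_seed(seed, list(alpha = random_cdr3(M, cfg_fixed_len),
                                 beta = random_cdr3(M, cfg_fixed_len)))
  lapply(seq_len(M), function(m) {
    list(v_alpha = va[m], j_alpha = ja[(m - 1) %% length(ja) + 1],
         v_beta = vb[m], j_beta = jb[(m - 1) %% length(jb) + 1],
         motif_alpha = motifs$alpha[m], motif_beta = motifs$beta[m])
  })
}

# Apply per-position substitution noise to motif copies (active RNG).
mutate_motif <- function(motif, n, noise_rate, aa_freq, lead_cys) {
  if (n == 0) return(character(0))
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  L <- length(chars)
  m <- matrix(rep(chars, each = n), nrow = n)
  from <- if (lead_cys) 2L else 1L
  if (L >= from && noise_rate > 0) {
    idx <- which(matrix(runif(n * L), n, L) < noise_rate)
    idx <- idx[((idx - 1) %/% n + 1) >= from]  # spare the leading C
    if (length(idx) > 0) {
      m[idx] <- sample(AA_LETTERS, length(idx), replace = TRUE,
                       prob = aa_freq)
    }
  }
  apply(m, 1, paste, collapse = "")
}

#' Generate an epitope-specific repertoire from a mixture of modes
#'
#' Each clone samples a binding mode (or the background, with probability
#' `false_positive_fraction`), inherits the mode's anchored genes, and
#' reproduces the mode's CDR3 motifs with per-position noise.
#'
#' @param config a [mixture_config()].
#' @param background the [background_config()] supplying the amino acid
#'   distribution for substitutions and the false-positive draws.
#' @return a repertoire tibble labeled with `config$epitope`.
#' @export
generate_specific <- function(config, background) {
  stopifnot(inherits(config, "mixture_config"),
            inherits(background, "background_config"))
  n <- config$n_clones
  out <- with_seed(child_seed(config$seed, 2), {
    is_fp <- runif(n) < config$false_positive_fraction
    n_fp <- sum(is_fp)
    rows <- sample_background_rows(n, background, id_prefix = "sp")
    if (n_fp < n) {
      idx <- which(!is_fp)
      mode_of <- sample.int(length(config$modes), length(idx),
                            replace = TRUE, prob = config$mode_weights)
      for (m in seq_along(config$modes)) {
        sel <- idx[mode_of == m]
        if (length(sel) == 0) next
        md <- config$modes[[m]]
        rows$v_alpha[sel] <- md$v_alpha
        rows$j_alpha[sel] <- md$j_alpha
        rows$v_beta[sel] <- md$v_beta
        rows$j_beta[sel] <- md$j_beta
        rows$cdr3_alpha[sel] <- mutate_motif(md$motif_alpha, length(sel),
                                             config$noise_rate,
                                             background$aa_freq,
                                             background$lead_cys)
        rows$cdr3_beta[sel] <- mutate_motif(md$motif_beta, length(sel),
                                            config$noise_rate,
                                            background$aa_freq,
                                            background$lead_cys)
      }
    }
    rows$epitope <- rep(config$epitope, n)
    rows$clone_id <- if (n > 0) sprintf("%s_%06d", config$epitope,
                                        seq_len(n)) else character(0)
    rows
  })
  new_repertoire(out, list(source = "simulated_mixture",
                           n_input = n, n_dropped = 0, n_retained = n))
}

#' Sweep over numbers of binding modes
#'
#' Simulates one epitope-specific repertoire per entry of `mode_counts`
#' (each with that many disjoint equal-weight modes) and computes the
#' local relevancies of the alpha chain, beta chain and paired receptor
#' plus the local alpha-beta interaction information. Background
#' coincidence probabilities are evaluated exactly from the background
#' configuration, mirroring a model-based background distribution; they
#' are constant across epitopes, so differences and slopes across the
#' sweep reflect the specific repertoires alone.
#'
#' @param mode_counts integer vector; entry e simulates an epitope with
#'   `mode_counts[e]` modes.
#' @param background a [background_config()].
#' @param n_clones clones per simulated epitope.
#' @param noise_rate per-position motif substitution probability.
#' @param motif_length CDR3 template length.
#' @param seed root seed; each epitope uses independent child streams.
#' @return a tibble with columns `epitope`, `n_modes`, `i2_alpha`,
#'   `i2_beta`, `i2_tcr`, `i2_int` (bits).
#' @export
mixture_sweep <- function(mode_counts, background, n_clones = 2000,
                          noise_rate = 0.1, motif_length = 12, seed = 1) {
  feats <- c(alpha = "alpha", beta = "beta", tcr = "tcr")
  pc_bg <- vapply(feats, function(f) pc_background_exact(background, f),
                  numeric(1))
  rows <- lapply(seq_along(mode_counts), function(e) {
    M <- mode_counts[e]
    modes <- make_disjoint_modes(M, background,
                                 motif_length = motif_length,
                                 seed = child_seed(seed, 100 + e))
    cfg <- mixture_config(modes, noise_rate = noise_rate,
                          n_clones = n_clones,
                          epitope = sprintf("sim%02d", e),
                          seed = child_seed(seed, 200 + e))
    tab <- generate_specific(cfg, background)
    i2 <- vapply(feats, function(f) {
      log2(pc_pairs(extract_feature(tab, f))$p_hat / pc_bg[[f]])
    }, numeric(1))
    tibble(epitope = cfg$epitope, n_modes = M,
           i2_alpha = i2[["alpha"]], i2_beta = i2[["beta"]],
           i2_tcr = i2[["tcr"]],
           i2_int = i2[["tcr"]] - i2[["alpha"]] - i2[["beta"]])
  })
  do.call(rbind, rows)
}

#' Spike-in classification experiment
#'
#' Validates the posterior-odds relation \eqn{O_{post} = 2^{I_2}
#' O_{prior}} by simulation. Queries are drawn from the two-component
#' mixture: with probability `spike_fraction` from the specific feature
#' distribution, otherwise from the background distribution. Each query
#' is classified specific if it matches a fresh reference draw from the
#' specific distribution; the empirical posterior is the fraction of true
#' spikes among match-positives, the prediction comes from the exact
#' coincidence ratio. The prediction's cross-match term uses
#' \eqn{p_C[X]}, valid when specific binding is independent of background
#' generation probability (exactly so for a uniform background).
#'
#' @param spike_fraction numeric vector of prior spike fractions P(pi),
#'   one experiment per value.
#' @param specific_dist named probability vector of the feature among
#'   specific sequences.
#' @param background_dist named probability vector of the feature in the
#'   background.
#' @param n_queries queries per experiment.
#' @param seed root seed (independent stream per prior value).
#' @return a tibble with columns `prior`, `prior_odds`, `bits`,
#'   `n_matches`, `empirical_posterior`, `predicted_posterior`.
#' @export
spike_in_experiment <- function(spike_fraction, specific_dist,
                                background_dist, n_queries = 1e5,
                                seed = 1) {
  check_dist(specific_dist, "specific_dist")
  check_dist(background_dist, "background_dist")
  empty <- tibble(prior = numeric(0), prior_odds = numeric(0),
                  bits = numeric(0), n_matches = integer(0),
                  empirical_posterior = numeric(0),
                  predicted_posterior = numeric(0))
  if (n_queries == 0 || length(spike_fraction) == 0) return(empty)
  bits <- log2(pc_exact(specific_dist) / pc_exact(background_dist))
  rows <- lapply(seq_along(spike_fraction), function(i) {
    p <- spike_fraction[i]
    stopifnot(p > 0, p < 1)
    res <- with_seed(child_seed(seed, 300 + i), {
      is_spike <- runif(n_queries) < p
      vals <- character(n_queries)
      ns <- sum(is_spike)
      if (ns > 0) vals[is_spike] <- sample(names(specific_dist), ns,
                                           replace = TRUE,
                                           prob = specific_dist)
      if (ns < n_queries) {
        vals[!is_spike] <- sample(names(background_dist),
                                  n_queries - ns, replace = TRUE,
                                  prob = background_dist)
      }
      refs <- sample(names(specific_dist), n_queries, replace = TRUE,
                     prob = specific_dist)
      hit <- vals == refs
      list(n_matches = sum(hit),
           emp = if (any(hit)) mean(is_spike[hit]) else NA_real_)
    })
    o_prior <- prob_to_odds(p)
    tibble(prior = p, prior_odds = o_prior, bits = bits,
           n_matches = res$n_matches,
           empirical_posterior = res$emp,
           predicted_posterior = odds_to_prob(
             posterior_odds(o_prior, bits)))
  })
  do.call(rbind, rows)
}
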