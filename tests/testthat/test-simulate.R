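test_that("generators are pure functions of their seed", {
  cfg <- background_config(n_clones = 300, seed = 17)
  expect_identical(as.data.frame(generate_background(cfg)),
                   as.data.frame(generate_background(cfg)))
  cfg2 <- background_config(n_clones = 300, seed = 18)
  expect_false(identical(generate_background(cfg)$cdr3_beta,
                         generate_background(cfg2)$cdr3_beta))
  modes <- make_disjoint_modes(3, cfg, seed = 4)
  mx <- mixture_config(modes, n_clones = 200, seed = 5)
  expect_identical(as.data.frame(generate_specific(mx, cfg)),
                   as.data.frame(generate_specific(mx, cfg)))
  # n_clones = 0 -> empty table
  expect_equal(nrow(generate_background(
    background_config(n_clones = 0))), 0)
})

test_that("background marginals converge to the configured usage", {
  cfg <- background_config(n_clones = 10000, seed = 21)
  bg <- generate_background(cfg)
  freq <- table(factor(bg$v_beta, levels = names(cfg$v_beta))) /
    nrow(bg)
  se <- sqrt(cfg$v_beta * (1 - cfg$v_beta) / nrow(bg))
  expect_true(all(abs(freq - cfg$v_beta) < 3 * se))
  # CDR3s respect the leading-cysteine convention and the length support
  expect_true(all(substr(bg$cdr3_beta, 1, 1) == "C"))
  expect_true(all(nchar(bg$cdr3_alpha) %in%
                    as.integer(names(cfg$cdr3_length))))
})

test_that("single-mode, noiseless, contamination-free epitopes are
           fully anchored", {
  cfg <- background_config(seed = 23)
  modes <- make_disjoint_modes(1, cfg, seed = 6)
  mx <- mixture_config(modes, noise_rate = 0, n_clones = 50, seed = 7)
  tab <- generate_specific(mx, cfg)
  expect_equal(unique(tab$v_beta), modes[[1]]$v_beta)
  expect_equal(unique(tab$j_alpha), modes[[1]]$j_alpha)
  expect_equal(unique(tab$cdr3_beta), modes[[1]]$motif_beta)
  expect_equal(unique(tab$epitope), "epitope1")
})

test_that("pure false-positive epitopes carry no information", {
  cfg <- background_config(n_clones = 2000, seed = 25)
  bg <- generate_background(cfg)
  modes <- make_disjoint_modes(2, cfg, seed = 8)
  mx <- mixture_config(modes, false_positive_fraction = 1,
                       n_clones = 1500, seed = 9)
  tab <- generate_specific(mx, cfg)
  out <- relevancy(tab, bg, "vb")
  expect_lt(abs(out$bits), 0.2)
})

test_that("exact background coincidence probabilities match sampling
           and enumeration", {
  cfg <- background_config(n_clones = 20000, seed = 27)
  bg <- generate_background(cfg)
  for (f in c("vb", "jb", "lenb", "chargeb")) {
    est <- pc_pairs(extract_feature(bg, f))$p_hat
    exact <- pc_background_exact(cfg, f)
    expect_lt(abs(est - exact) / exact, 0.1)
  }
  # product feature = product of component exact values (independence)
  expect_equal(pc_background_exact(cfg, "vb+jb"),
               pc_background_exact(cfg, "vb") *
                 pc_background_exact(cfg, "jb"))
  # charge coincidence vs full enumeration on a tiny configuration
  small <- background_config(
    cdr3_length = c(`2` = 0.6, `3` = 0.4),
    aa_freq = setNames(rep(0.05, 20), AA20))
  body <- list(AA20, as.vector(outer(AA20, AA20, paste0)))
  probs <- c(rep(0.6 / 20, 20), rep(0.4 / 400, 400))
  charges <- net_charge(paste0("C", unlist(body)))
  pc_enum <- oracle_pc(as.vector(tapply(probs, charges, sum)))
  expect_equal(pc_background_exact(small, "chargeb"), pc_enum,
               tolerance = 1e-12)
  # cdr3 exact value vs direct enumeration on the same configuration
  key <- paste0("C", unlist(body))
  pc_cdr3_enum <- oracle_pc(as.vector(tapply(probs, key, sum)))
  expect_equal(pc_background_exact(small, "cdr3b"), pc_cdr3_enum,
               tolerance = 1e-12)
})

test_that("doubling the number of disjoint modes shifts local scores by
           one bit", {
  # exact mixture arithmetic: M disjoint equal-weight modes with equal
  # within-mode coincidence q give pc = q / M, so each doubling of M
  # costs one bit of per-chain relevancy and adds one bit of synergy
  q <- 0.2
  pc_bg <- 1e-6
  for (M in c(1, 2, 4, 8)) {
    i2_single <- log2((q / M) / pc_bg)
    i2_joint <- log2((q^2 / M) / pc_bg^2)
    i2_int <- i2_joint - 2 * i2_single
    expect_equal(i2_int, log2(M), tolerance = 1e-12)
    expect_equal(log2((q / (2 * M)) / pc_bg), i2_single - 1,
                 tolerance = 1e-12)
  }
})

test_that("mixture_sweep returns one row per epitope with decreasing
           per-chain information in the mode count", {
  cfg <- background_config(seed = 29)
  sw <- mixture_sweep(c(1, 4, 16), cfg, n_clones = 800, seed = 31)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$n_modes, c(1, 4, 16))
  expect_true(all(diff(sw$i2_alpha) < 0))
  expect_true(all(diff(sw$i2_int) > 0))
})

test_that("conditioning on gene usage unmasks length information in
           mode-structured repertoires", {
  cfg <- background_config(n_clones = 4000, seed = 33)
  bg <- generate_background(cfg)
  # two modes with different CDR3beta lengths tied to different V genes
  m1 <- make_disjoint_modes(2, cfg, motif_length = 10, seed = 10)
  m2 <- make_disjoint_modes(2, cfg, motif_length = 16, seed = 11)
  modes <- list(m1[[1]], m2[[2]])
  mx <- mixture_config(modes, n_clones = 1000, noise_rate = 0.1,
                       seed = 12)
  tab <- generate_specific(mx, cfg)
  plain <- relevancy(tab, bg, "lenb")$bits
  cond <- conditional_relevancy(tab, bg, "lenb", "vb+jb")$bits
  expect_gt(cond, plain)
})

test_that("spike-in experiments reproduce the posterior-odds relation", {
  # zero-information feature: posterior equals prior
  p <- setNames(rep(0.25, 4), letters[1:4])
  out <- spike_in_experiment(0.2, p, p, n_queries = 40000, seed = 35)
  expect_equal(out$bits, 0)
  se <- sqrt(0.2 * 0.8 / out$n_matches)
  expect_lt(abs(out$empirical_posterior - 0.2), 3 * se)
  # deterministic specific feature over a uniform background
  bgd <- setNames(rep(1 / 8, 8), letters[1:8])
  spd <- setNames(c(1, rep(0, 7)), letters[1:8])
  out <- spike_in_experiment(0.05, spd, bgd, n_queries = 40000,
                             seed = 37)
  expect_equal(out$bits, 3)
  se <- sqrt(out$predicted_posterior *
               (1 - out$predicted_posterior) / out$n_matches)
  expect_lt(abs(out$empirical_posterior - out$predicted_posterior),
            3 * se)
  # n_queries = 0 -> empty table
  expect_equal(nrow(spike_in_experiment(0.1, spd, bgd, n_queries = 0)),
               0)
})

test_that("odr_slope fits exact lines, inverts under axis swap, and
           matches closed-form orthogonal regression", {
  x <- seq(0, 10, length.out = 20)
  y <- 2 * x + 1
  fit <- odr_slope(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  swap <- odr_slope(y, x)
  expect_equal(swap$slope, 1 / fit$slope, tolerance = 1e-6)
  # noisy line recovery with errors on both axes
  set.seed(39)
  xt <- runif(50, 0, 10)
  xo <- xt + rnorm(50, sd = 0.2)
  yo <- -1.5 * xt + 4 + rnorm(50, sd = 0.2)
  fit <- odr_slope(xo, yo, x_se = 0.2, y_se = 0.2)
  expect_equal(fit$slope, -1.5, tolerance = 0.1)
  expect_true(fit$slope_se > 0)
  # equal-error ODR equals the principal-axis solution
  expect_equal(odr_slope(xo, yo)$slope, oracle_tls_slope(xo, yo),
               tolerance = 1e-6)
})
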