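test_that("relevancy_exact reproduces hand-computed values", {
  # uniform background over 16 values, two constant-valued epitopes
  expect_equal(relevancy_exact(list(1, 1), rep(1 / 16, 16)), 4.0)
  # background (0.5, 0.25, 0.25); epitope uniform on the last two values
  expect_equal(relevancy_exact(list(c(0.5, 0.5)), c(0.5, 0.25, 0.25)),
               log2(0.5 / 0.375))
  # specific identical to background -> 0 bits
  p <- c(0.4, 0.35, 0.25)
  expect_equal(relevancy_exact(list(p, p), p), 0)
})

test_that("sampled relevancy agrees with hand construction and is ~0 for
           background-distributed groups", {
  # epitopes constant-valued on distinct values, background all distinct:
  # p_C[X|Pi] = 1; p_hat background from pair counting
  spec <- toy_repertoire(8,
    v_beta = rep(c("TRBV1", "TRBV2"), each = 4),
    epitope = rep(c("e1", "e2"), each = 4))
  bg <- toy_repertoire(8, v_beta = paste0("TRBV", 1:8))
  expect_warning(out <- relevancy(spec, bg, "vb"), "undefined")
  expect_true(is.na(out$bits))  # zero background coincidences
  bg$v_beta <- rep(paste0("TRBV", 1:4), 2)
  out <- relevancy(spec, bg, "vb")
  expect_equal(out$bits, log2(1 / pc_pairs(bg$v_beta)$p_hat))
  expect_equal(out$n_specific, 8L)
  expect_equal(out$n_background, 8L)
  # specific drawn from the background distribution: bits near 0,
  # bootstrap CI covers 0
  set.seed(19)
  vs <- sample(paste0("TRBV", 1:4), 300, replace = TRUE)
  spec <- toy_repertoire(300, v_beta = vs,
                         epitope = rep(c("e1", "e2"), 150))
  bg <- toy_repertoire(400,
    v_beta = sample(paste0("TRBV", 1:4), 400, replace = TRUE))
  out <- relevancy(spec, bg, "vb", bootstrap = 200, seed = 1)
  expect_lt(out$ci_low, 0 + 1e-9)
  expect_gt(out$ci_high, out$bits - 1e-9)
})

test_that("local relevancy restricts to one epitope group", {
  spec <- toy_repertoire(8,
    v_beta = c(rep("TRBV1", 4), c("TRBV1", "TRBV2", "TRBV3", "TRBV4")),
    epitope = rep(c("e1", "e2"), each = 4))
  bg <- toy_repertoire(8, v_beta = rep(paste0("TRBV", 1:4), 2))
  l1 <- local_relevancy(spec, bg, "vb", epitope = "e1")
  expect_equal(l1$bits, log2(1 / pc_pairs(bg$v_beta)$p_hat))
  expect_equal(l1$scope, "local:e1")
  # no coincidences in e2 -> undefined with diagnostic
  expect_warning(l2 <- local_relevancy(spec, bg, "vb", epitope = "e2"),
                 "undefined")
  expect_true(is.na(l2$bits))
  expect_error(local_relevancy(spec, bg, "vb"), "epitope")
})

test_that("global relevancy lies between local extremes under uniform
           weights", {
  set.seed(23)
  bgv <- sample(paste0("TRBV", 1:5), 300, replace = TRUE)
  bg <- toy_repertoire(300, v_beta = bgv)
  spec <- toy_repertoire(120,
    v_beta = c(rep("TRBV1", 40),
               sample(paste0("TRBV", 1:3), 80, replace = TRUE)),
    epitope = rep(c("e1", "e2"), c(40, 80)))
  g <- relevancy(spec, bg, "vb")$bits
  l <- vapply(c("e1", "e2"), function(e) {
    local_relevancy(spec, bg, "vb", epitope = e)$bits
  }, numeric(1))
  expect_gte(g, min(l) - 1e-9)
  expect_lte(g, max(l) + 1e-9)
})

test_that("conditional_relevancy_exact matches enumeration and limiting
           cases", {
  set.seed(29)
  for (rep in 1:8) {
    nx <- sample(2:5, 1); ny <- sample(2:4, 1); k <- sample(1:3, 1)
    bgj <- rand_joint(nx, ny)
    spj <- lapply(seq_len(k), function(i) rand_joint(nx, ny))
    p_pi <- rand_dist(k)
    expect_equal(conditional_relevancy_exact(bgj, spj, p_pi),
                 oracle_cond_relevancy(bgj, spj, p_pi),
                 tolerance = 1e-9)
  }
  # Y = X: fully redundant, 0 bits
  px_bg <- rand_dist(4); px_sp <- rand_dist(4)
  expect_equal(conditional_relevancy_exact(diag(px_bg),
                                           list(diag(px_sp))), 0,
               tolerance = 1e-12)
  # Y constant: reduces to plain relevancy
  expect_equal(
    conditional_relevancy_exact(matrix(px_bg, ncol = 1),
                                list(matrix(px_sp, ncol = 1))),
    relevancy_exact(list(px_sp), px_bg), tolerance = 1e-12)
})

test_that("sampled conditional_relevancy: redundant and informative
           strata behave correctly", {
  spec <- toy_repertoire(12,
    v_beta = rep(c("TRBV1", "TRBV2"), each = 6),
    j_beta = rep(c("TRBJ1", "TRBJ2"), 6),
    epitope = rep("e1", 12))
  bg <- toy_repertoire(20,
    v_beta = sample(rep(c("TRBV1", "TRBV2"), each = 10)),
    j_beta = rep(c("TRBJ1", "TRBJ2"), 10))
  # conditioning a feature on itself leaves nothing
  out <- conditional_relevancy(spec, bg, "vb", "vb")
  expect_equal(out$bits, 0)
  expect_equal(out$conditioning, "vb")
})

test_that("interaction_exact: synergy, redundancy and independence", {
  # background uniform on {00,01,10,11}; specific uniform on {00,11}
  bgj <- matrix(0.25, 2, 2)
  spj <- diag(c(0.5, 0.5))
  expect_equal(interaction_exact(bgj, list(spj)), 1.0,
               tolerance = 1e-12)
  expect_equal(oracle_interaction(bgj, list(spj), 1), 1.0)
  # Y an exact copy of X carrying 1 bit: fully redundant, -1 bit
  bgj <- diag(rep(0.25, 4))
  spj <- diag(c(0.5, 0.5, 0, 0))
  expect_equal(interaction_exact(bgj, list(spj)), -1.0,
               tolerance = 1e-12)
  # X, Y independent in background and specific -> 0
  set.seed(31)
  px_b <- rand_dist(3); py_b <- rand_dist(4)
  px_s <- rand_dist(3); py_s <- rand_dist(4)
  expect_equal(interaction_exact(outer(px_b, py_b),
                                 list(outer(px_s, py_s))), 0,
               tolerance = 1e-9)
  # random cases against the enumeration oracle
  for (rep in 1:8) {
    k <- sample(1:3, 1)
    bgj <- rand_joint(3, 3)
    spj <- lapply(seq_len(k), function(i) rand_joint(3, 3))
    p_pi <- rand_dist(k)
    expect_equal(interaction_exact(bgj, spj, p_pi),
                 oracle_interaction(bgj, spj, p_pi), tolerance = 1e-9)
  }
})

test_that("coincidence mutual information is symmetric on exact joints", {
  set.seed(37)
  for (rep in 1:10) {
    m <- rand_joint(sample(2:5, 1), sample(2:5, 1))
    p_x <- rowSums(m); p_y <- colSums(m)
    i_xy <- log2(tcrinfo:::pc_cond_from_joint(m) / pc_exact(p_x))
    i_yx <- log2(tcrinfo:::pc_cond_from_joint(t(m)) / pc_exact(p_y))
    expect_equal(i_xy, i_yx, tolerance = 1e-9)
  }
})

test_that("sampled interaction_information recovers synergy of an
           XOR-style construction", {
  set.seed(41)
  n <- 400
  # background: V and J independent uniform; specific: V and J matched
  vs <- sample(c("TRBV1", "TRBV2"), n, TRUE)
  spec <- toy_repertoire(n, v_beta = vs,
                         j_beta = ifelse(vs == "TRBV1", "TRBJ1", "TRBJ2"),
                         epitope = "e1")
  bg <- toy_repertoire(n,
    v_beta = sample(c("TRBV1", "TRBV2"), n, TRUE),
    j_beta = sample(c("TRBJ1", "TRBJ2"), n, TRUE))
  out <- interaction_information(spec, bg, "vb", "jb")
  expect_gt(out$bits, 0.7)   # ~1 bit of synergy
  expect_lt(out$bits, 1.3)
  # local variant restricted to the only epitope agrees
  out_local <- interaction_information(spec, bg, "vb", "jb",
                                       local = "e1")
  expect_equal(out_local$bits, out$bits)
})

test_that("relevancy_matrix is symmetric with relevancies on the
           diagonal; interaction grid follows", {
  set.seed(43)
  n <- 200
  vs <- sample(c("TRBV1", "TRBV2"), n, TRUE)
  spec <- toy_repertoire(n, v_beta = vs,
                         j_beta = ifelse(vs == "TRBV1", "TRBJ1", "TRBJ2"),
                         epitope = "e1")
  bg <- toy_repertoire(n,
    v_beta = sample(c("TRBV1", "TRBV2"), n, TRUE),
    j_beta = sample(c("TRBJ1", "TRBJ2"), n, TRUE))
  m <- relevancy_matrix(spec, bg, c("vb", "jb"))
  expect_equal(m["vb", "jb"], m["jb", "vb"])
  expect_equal(m["vb", "vb"], relevancy(spec, bg, "vb")$bits)
  im <- interaction_matrix(m)
  expect_equal(im["vb", "jb"],
               m["vb", "jb"] - m["vb", "vb"] - m["jb", "jb"])
  expect_equal(diag(im), c(vb = 0, jb = 0))
})
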