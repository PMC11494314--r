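# Independent direct-formula oracles, written as naive loops so they
# share no code path with the package implementation.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_pc <- function(p) {
  s <- 0
  for (pi in p) s <- s + pi * pi
  s
}

oracle_pc_cond <- function(cond, p_y) {
  p_y <- p_y / sum(p_y)
  rho <- p_y^2 / sum(p_y^2)
  s <- 0
  for (i in seq_along(cond)) s <- s + rho[i] * oracle_pc(cond[[i]])
  s
}

oracle_relevancy <- function(cond, bg, p_pi) {
  log2(oracle_pc_cond(cond, p_pi) / oracle_pc(bg))
}

# pc[X|Y] from a joint matrix P(x, y), x rows / y cols
oracle_pc_x_given_y <- function(m) {
  py <- colSums(m)
  conds <- list()
  w <- numeric(0)
  for (j in seq_len(ncol(m))) {
    if (py[j] > 0) {
      conds <- c(conds, list(m[, j] / py[j]))
      w <- c(w, py[j])
    }
  }
  oracle_pc_cond(conds, w)
}

oracle_cond_relevancy <- function(bg_joint, spec_joints, p_pi) {
  conds <- list()
  w <- numeric(0)
  for (i in seq_along(spec_joints)) {
    m <- spec_joints[[i]]
    py <- colSums(m)
    for (j in seq_len(ncol(m))) {
      if (py[j] > 0) {
        conds <- c(conds, list(m[, j] / py[j]))
        w <- c(w, p_pi[i] * py[j])
      }
    }
  }
  log2(oracle_pc_cond(conds, w) / oracle_pc_x_given_y(bg_joint))
}

oracle_interaction <- function(bg_joint, spec_joints, p_pi) {
  rel <- function(f) {
    oracle_relevancy(lapply(spec_joints, f), f(bg_joint), p_pi)
  }
  rel(function(m) as.vector(m)) - rel(rowSums) - rel(colSums)
}

# all-unordered-pairs coincidence fraction
oracle_pc_pairs <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(NA_real_)
  hits <- 0
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      if (values[i] == values[j]) hits <- hits + 1
    }
  }
  hits / tot
}

# textbook dynamic-programming edit distance
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# exact Eq.-18 style probability that two draws are at distance delta
oracle_pc_delta <- function(p, strings, delta) {
  s <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (oracle_levenshtein(strings[i], strings[j]) == delta) {
        s <- s + p[i] * p[j]
      }
    }
  }
  s
}

# all-pairs distance fraction at delta on a sample of strings
oracle_pair_fraction_at <- function(strings, delta) {
  strings <- strings[!is.na(strings)]
  n <- length(strings)
  hits <- 0
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      if (oracle_levenshtein(strings[i], strings[j]) == delta) {
        hits <- hits + 1
      }
    }
  }
  hits / tot
}

# closed-form orthogonal (total least squares) regression slope for
# equal errors: principal-axis solution
oracle_tls_slope <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
}

# random probability vector (call under set.seed)
rand_dist <- function(k) {
  p <- -log(runif(k))
  p / sum(p)
}

# random joint matrix P(x, y) with no empty rows/cols
rand_joint <- function(nx, ny) {
  m <- matrix(-log(runif(nx * ny)), nx, ny)
  m / sum(m)
}
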