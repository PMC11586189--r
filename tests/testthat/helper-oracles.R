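# Independent oracles, coded from first principles and kept deliberately
# naive (explicit loops, direct formulas) so they do not share code paths
# with the implementation they check.

# Weighted-sum potential: loop over samples, markers and genera.
oracle_potential <- function(rel, coeff) {
  out <- matrix(0, nrow(rel), ncol(coeff),
                dimnames = list(rownames(rel), colnames(coeff)))
  for (s in seq_len(nrow(rel))) {
    for (m in seq_len(ncol(coeff))) {
      acc <- 0
      for (g in colnames(rel)) {
        if (g %in% rownames(coeff)) acc <- acc + rel[s, g] * coeff[g, m]
      }
      out[s, m] <- 100 * acc
    }
  }
  out
}

# Fixed-intercept log-linear slope via lm() on the shifted response.
oracle_slope_lm <- function(t, y, intercept = 100) {
  unname(stats::coef(stats::lm(I(log(y) - log(intercept)) ~ 0 + t)))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction.
oracle_kw_H <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 0
  for (i in seq_along(groups)) {
    Ri <- sum(r[idx == i])
    H <- H + Ri^2 / sum(idx == i)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- table(vals)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Dunn z for one pair, written independently from scratch.
oracle_dunn_z <- function(groups, i, j) {
  vals <- unlist(groups, use.names = FALSE)
  idx <- rep(seq_along(groups), lengths(groups))
  r <- rank(vals)
  N <- length(vals)
  ties <- table(vals)
  A <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  num <- mean(r[idx == i]) - mean(r[idx == j])
  num / sqrt(A * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
}

# Classical PCA via eigendecomposition of the column-centered covariance.
oracle_pca <- function(m) {
  cm <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cm), symmetric = TRUE)
  list(scores = cm %*% ev$vectors, values = ev$values)
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis statistic.
oracle_perm_p <- function(groups, B = 10000L, seed = 42L) {
  vals <- unlist(groups, use.names = FALSE)
  sizes <- lengths(groups)
  H_obs <- oracle_kw_H(groups)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    perm <- sample(vals)
    gs <- split(perm, rep(seq_along(sizes), sizes))
    if (oracle_kw_H(gs) >= H_obs - 1e-12) hits <- hits + 1L
  }
  p_hat <- hits / B
  se <- sqrt(p_hat * (1 - p_hat) / B)
  list(p = p_hat, ci = c(p_hat - 1.96 * se, p_hat + 1.96 * se))
}

# Random relative abundance table over named genera.
random_rel_table <- function(n_samples, genera, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_samples * length(genera)), n_samples,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)), genera))
  m <- m / rowSums(m)
  abundance_table(m, mode = "relative")
}
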