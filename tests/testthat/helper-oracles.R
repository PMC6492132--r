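# Independent oracles and small fixtures used across tests.

# Textbook partial correlation by residual regression: correlate the
# residuals of each pair after regressing out all other nodes.
residual_partial_correlation <- function(ts) {
  n <- nrow(ts)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- cbind(1, t(ts[-c(i, j), , drop = FALSE]))
      ri <- lm.fit(others, ts[i, ])$residuals
      rj <- lm.fit(others, ts[j, ])$residuals
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

# Magnitude of the digital transfer function b(z)/a(z) at frequency f (Hz).
transfer_gain <- function(coefs, f, fs) {
  z <- exp(-2i * pi * f / fs)
  abs(sum(coefs$b * z^(seq_along(coefs$b) - 1)) /
      sum(coefs$a * z^(seq_along(coefs$a) - 1)))
}

# Rank-based AUC of scores against binary labels (Mann-Whitney identity).
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Node series whose *sample* covariance equals S exactly: empirically
# whitened Gaussian noise remixed through chol(S).
series_with_exact_cov <- function(S, n_timepoints, seed = 1) {
  n <- nrow(S)
  set.seed(seed)
  Z <- matrix(rnorm(n * n_timepoints), n, n_timepoints)
  Z <- Z - rowMeans(Z)
  W <- solve(t(chol(cov(t(Z)))), Z)  # sample covariance of W = I
  t(chol(S)) %*% W
}

# Small study dataset for discrimination tests.
tiny_dataset <- function(seed = 1, n_subjects = 5, n_states = 3, n_nodes = 6,
                         n_timepoints = 120, ...) {
  cfg <- simulation_config(n_subjects = n_subjects, n_states = n_states,
                           n_nodes = n_nodes, n_timepoints = n_timepoints,
                           bands = data.frame(low = 0.01, high = 0.3),
                           seed = seed, ...)
  simulate_dataset(cfg)
}

# Permute state labels within each subject (design-preserving shuffle).
permute_states_within_subject <- function(table) {
  for (s in unique(table$subject)) {
    idx <- which(table$subject == s)
    table$state[idx] <- sample(table$state[idx])
  }
  table
}
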