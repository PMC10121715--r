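# Shared fixtures, built in code.

# Fast EM settings for recovery tests: enough Monte-Carlo samples to be
# stable at the 9-point benchmark scale without the full budget.
em_fast <- function(seed = NULL) em_control(M = 3000, max_iter = 12, seed = seed)

# A small smooth decomposition with one gain-like component.
toy_decomp <- function(sigma1_2 = 0.16, sigma0_2 = 0, K = 1,
                       grid = benchmark_grid()) {
  m <- length(grid$values)
  phis <- matrix(rep(1 / sqrt(m), m), m, 1)
  sig <- sigma1_2
  if (K == 2) {
    phis <- cbind(phis, fluctuation_fpc("shift", grid = grid))
    phis[, 2] <- phis[, 2] - phis[, 1] %*% crossprod(phis[, 1, drop = FALSE], phis[, 2])
    phis[, 2] <- phis[, 2] / sqrt(sum(phis[, 2]^2))
    sig <- c(sigma1_2, sigma1_2 / 2)
  }
  tuning_decomposition(grid, log(benchmark_tuning_curve(grid$values)),
                       phis, sig, sigma0_2)
}

# Independent 1-D quadrature oracle for the Poisson--log-normal posterior:
# prior N(f, s2) on the log rate, likelihood Poisson(n | exp(l) * dt).
quadrature_posterior_mean <- function(n, f, s2, dt = 1, ngrid = 20001) {
  l <- seq(f - 8 * sqrt(s2), f + 8 * sqrt(s2), length.out = ngrid)
  logq <- stats::dnorm(l, f, sqrt(s2), log = TRUE) +
    n * (l + log(dt)) - exp(l) * dt
  w <- exp(logq - max(logq))
  sum(l * w) / sum(w)
}

# Pooled first-fPC score-recovery correlation across the four benchmark
# fluctuation types for one base seed and one method.
pooled_recovery <- function(seed, method, em = em_control(M = 10000),
                            K = 9) {
  kinds <- c("gain", "additive", "shift", "sharpen")
  est <- c()
  tru <- c()
  for (j in seq_along(kinds)) {
    b <- build_benchmark(kinds[j], seed = seed * 100 + j)
    emj <- em
    emj$seed <- seed * 100 + 50 + j
    fit <- pfpca(b$counts, K = K, method = method, em = emj)
    sr <- score_recovery(fit$scores[, 1], fit$phis[, 1],
                         b$scores[, 1], b$truth$phis[, 1])
    est <- c(est, sr$aligned_scores)
    tru <- c(tru, b$scores[, 1])
  }
  stats::cor(est, tru)
}
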