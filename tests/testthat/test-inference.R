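test_that("a point-mass prior pins the posterior at the prior mean", {
  f <- log(c(2, 5, 3))
  out <- pfpca_estep(c(0, 12, 1), f, matrix(0, 3, 3),
                     control = em_control(M = 500, seed = 1))
  expect_equal(out$post_mean, f)
  expect_equal(out$post_cov, matrix(0, 3, 3))
})

test_that("importance-sampling posterior matches a 1-D quadrature oracle", {
  cases <- expand.grid(n = c(0, 3, 12), f = log(c(1, 4)), s2 = c(0.09, 0.5))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    out <- pfpca_estep(cs$n, cs$f, matrix(cs$s2, 1, 1),
                       control = em_control(M = 200000, seed = 10 + i))
    oracle <- quadrature_posterior_mean(cs$n, cs$f, cs$s2)
    mc_se <- sqrt(out$post_cov[1, 1] / out$ess)
    expect_lt(abs(out$post_mean - oracle), 3 * mc_se + 1e-4)
  }
})

test_that("posterior shrinks toward the prior when counts sit at the prior mode", {
  f <- log(c(2, 5, 3, 4))
  n <- round(exp(f))
  out <- pfpca_estep(n, f, diag(0.01, 4),
                     control = em_control(M = 50000, seed = 2))
  expect_true(all(abs(out$post_mean - f) < 0.05))
})

test_that("M-step reproduces the closed-form averages", {
  u <- c(1, -2, 0.5)
  pm <- rbind(u, -u)
  pc <- array(0, c(3, 3, 2))
  up <- pfpca_mstep(pm, pc)
  expect_equal(up$f_hat, c(0, 0, 0))
  expect_equal(up$Sigma_hat, tcrossprod(u))
  # identical rows with zero posterior covariance collapse Sigma to zero
  up2 <- pfpca_mstep(rbind(u, u), pc)
  expect_equal(up2$Sigma_hat, matrix(0, 3, 3))
  expect_equal(up2$f_hat, u)
  expect_error(pfpca_mstep(matrix(u, 1, 3), array(0, c(3, 3, 1))),
               "at least 2 blocks")
})

test_that("EM recovers the mean log rate of fluctuation-free data", {
  g <- benchmark_grid()
  f_true <- log(2 + 5 * exp(-(g$values / 28)^2))   # rates >= 2 spikes/s
  dec <- tuning_decomposition(g, f_true, rep(1 / 3, 9), 0, 0)
  sim <- simulate_counts(dec, B = 200, seed = 5)
  em <- recover_latent_rates(sim$counts, em_fast(seed = 6))
  expect_lt(sqrt(mean((em$f_hat - f_true)^2)), 0.05)
  # posterior covariances stay PSD across the final E-step
  for (t in c(1, 100, 200))
    expect_gt(min(eigen(em$post$post_cov[, , t], symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
})

test_that("EM is deterministic given a seed and survives degenerate input", {
  b <- build_benchmark("gain", B = 10, seed = 1)
  e1 <- recover_latent_rates(b$counts, em_control(M = 500, max_iter = 3, seed = 9))
  e2 <- recover_latent_rates(b$counts, em_control(M = 500, max_iter = 3, seed = 9))
  expect_identical(e1$post$post_mean, e2$post$post_mean)
  expect_identical(e1$Sigma_hat, e2$Sigma_hat)
  # all-zero counts: finite output, strongly negative log rates, warning
  zero <- spike_count_matrix(matrix(0L, 2, 9), benchmark_grid())
  expect_warning(
    ez <- recover_latent_rates(zero, em_control(M = 500, max_iter = 3, seed = 1)),
    "no spikes")
  expect_true(all(is.finite(ez$f_hat)))
  expect_true(all(ez$f_hat < log(0.75)))
})

test_that("mean smoothing has the stated limiting behaviour", {
  g <- benchmark_grid()
  set.seed(21)
  pm <- matrix(rnorm(20 * 9, sd = 0.3), 20, 9) +
    rep(0.5 + 0.001 * (g$values / 10)^2, each = 20)
  # lambda = 0: the raw column mean, exactly
  expect_equal(smooth_mean(pm, g, lambda = 0)$f, colMeans(pm))
  # lambda -> infinity: the least-squares straight line in s
  line <- unname(fitted(lm(colMeans(pm) ~ g$values)))
  expect_equal(smooth_mean(pm, g, lambda = 1e8)$f, line, tolerance = 1e-4)
})

test_that("GCV smoothing beats the raw mean on a noisy quadratic", {
  g <- benchmark_grid()
  f_true <- 1 - (g$values / 90)^2
  err_gcv <- 0
  err_raw <- 0
  for (seed in 1:10) {
    set.seed(seed)
    pm <- matrix(rnorm(20 * 9, sd = 0.6), 20, 9) + rep(f_true, each = 20)
    err_gcv <- err_gcv + mean((smooth_mean(pm, g)$f - f_true)^2)
    err_raw <- err_raw + mean((colMeans(pm) - f_true)^2)
  }
  expect_lt(err_gcv, err_raw)
})

test_that("unpenalized fPCA equals a brute-force eigendecomposition", {
  g <- benchmark_grid()
  set.seed(31)
  dec <- toy_decomp(sigma1_2 = 0.6, sigma0_2 = 0.05, K = 2)
  sim <- simulate_counts(dec, B = 80, seed = 31)
  X <- sim$log_rates                       # exact log rates, no estimation
  f <- colMeans(X)
  fp <- penalized_fpca(X, f, g, K = 9, control = fpca_control(lambda_pc = 0))
  eg <- eigen(cov(sweep(X, 2, f)), symmetric = TRUE)
  for (k in 1:9) {
    v <- eg$vectors[, k]
    if (sum(v) < 0) v <- -v
    expect_equal(fp$phis[, k], v, tolerance = 1e-8)
  }
  expect_equal(sum(fp$shares), 1, tolerance = 1e-12)
})

test_that("fPCA recovers an exact rank-1 structure", {
  g <- benchmark_grid()
  phi <- fluctuation_fpc("shift", grid = g)
  set.seed(41)
  alpha <- rnorm(40)
  f0 <- log(benchmark_tuning_curve(g$values))
  X <- rep(f0, each = 40) + outer(alpha, phi)
  fp <- penalized_fpca(X, f0, g, K = 1, control = fpca_control(lambda_pc = 0))
  expect_gt(abs(sum(fp$phis[, 1] * phi)), 0.999)
  expect_gt(abs(cor(fp$scores[, 1], alpha)), 0.999)
})

test_that("fPCA reduces K on rank-deficient input with a warning", {
  g <- benchmark_grid()
  X <- outer(c(1, 2, 3), rep(1 / 3, 9))
  expect_warning(fp <- penalized_fpca(X, rep(0, 9), g, K = 5),
                 "reducing K")
  expect_lte(ncol(fp$phis), 2)
})

test_that("the roughness penalty prefers the smooth direction", {
  # two directions with identical sample variance: one smooth, one rough;
  # any positive penalty must pick the smooth one first
  g <- benchmark_grid()
  s <- g$values
  smooth <- cos(pi * s / 180); smooth <- smooth - mean(smooth)
  smooth <- smooth / sqrt(sum(smooth^2))
  rough <- rep(c(1, -1), length.out = 9) * c(1, 1, 1, 1, 1, 1, 1, 1, 1)
  rough <- rough - smooth * sum(rough * smooth)
  rough <- rough / sqrt(sum(rough^2))
  set.seed(51)
  a <- rnorm(60); b <- rnorm(60)
  X <- outer(a, smooth) + outer(b, rough)
  fp <- penalized_fpca(X, rep(0, 9), g, K = 1,
                       control = fpca_control(lambda_pc = 5))
  expect_gt(abs(sum(fp$phis[, 1] * smooth)), 0.9)
})
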