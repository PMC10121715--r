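test_that("benchmark tuning curve matches its closed form", {
  expect_equal(benchmark_tuning_curve(0), 5.5)
  s <- benchmark_grid()$values
  mu <- benchmark_tuning_curve(s)
  expect_equal(mu, rev(mu))                      # even function of s
  expect_true(all(mu > 0.5))
  expect_equal(benchmark_tuning_curve(20), 0.5 + 5 * exp(-0.5))
})

test_that("reverse-engineered fPCs have the stated shapes", {
  g <- benchmark_grid()
  mu0 <- benchmark_tuning_curve(g$values)
  for (k in c("gain", "additive", "shift", "sharpen")) {
    phi <- fluctuation_fpc(k, grid = g)
    expect_equal(sum(phi^2), 1, tolerance = 1e-12)
  }
  # gain: constant, each entry 1/sqrt(m)
  expect_equal(fluctuation_fpc("gain", grid = g), rep(1 / 3, 9))
  # shift: antisymmetric on the symmetric grid
  phi_s <- fluctuation_fpc("shift", grid = g)
  expect_equal(phi_s, -rev(phi_s), tolerance = 1e-12)
  # oracle: direct evaluation of log mu0(s +/- 6)
  d <- log(benchmark_tuning_curve(g$values + 6)) -
    log(benchmark_tuning_curve(g$values - 6))
  expect_equal(phi_s, d / sqrt(sum(d^2)), tolerance = 1e-12)
  # additive: non-constant, largest magnitude where mu0 is smallest
  phi_a <- fluctuation_fpc("additive", grid = g)
  expect_gt(diff(range(phi_a)), 0)
  expect_equal(which.max(abs(phi_a)), which.min(mu0))
})

test_that("additive fPC refuses a tuning curve at or below the 0.2 floor", {
  low <- function(s) rep(0.15, length(s))
  expect_error(fluctuation_fpc("additive", tuning = low),
               "non-positive.*stimulus")
})

test_that("structured covariance realizes the requested variance share", {
  phi <- rep(1 / 3, 9)
  sc <- structured_covariance(phi, 1.25, 0.8)
  expect_equal(sc$c, 1.25 / 36, tolerance = 1e-12)
  expect_equal(sc$share, 0.8, tolerance = 1e-12)
  # trace decomposition: structured variance over total
  expect_equal(1.25 / sum(diag(sc$Sigma)), 0.8, tolerance = 1e-12)
  eg <- eigen(sc$Sigma, symmetric = TRUE)
  expect_equal(eg$values[1], 1.25 + sc$c, tolerance = 1e-12)
  expect_equal(abs(sum(eg$vectors[, 1] * phi)), 1, tolerance = 1e-10)
  # share -> 1 limit sends the white-noise floor to zero
  expect_lt(structured_covariance(phi, 1.25, 0.9999)$c, 1e-4)
  expect_error(structured_covariance(phi, 1.25, 1), "between 0 and 1")
})

test_that("structured covariance is symmetric positive definite for valid inputs", {
  set.seed(42)
  for (i in 1:20) {
    m <- sample(4:12, 1)
    phi <- rnorm(m); phi <- phi / sqrt(sum(phi^2))
    sc <- structured_covariance(phi, runif(1, 0.1, 6), runif(1, 0.05, 0.95))
    expect_equal(sc$Sigma, t(sc$Sigma))
    expect_gt(min(eigen(sc$Sigma, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("degenerate simulation reduces to fixed-rate Poisson", {
  dec <- toy_decomp(sigma1_2 = 0, sigma0_2 = 0)
  # zero score variance is allowed by the model contract
  dec$sigma_k2 <- 0
  sim <- simulate_counts(dec, B = 2000, seed = 7)
  lam <- exp(dec$f) * dec$dt
  se <- sqrt(lam / 2000)
  expect_true(all(abs(colMeans(sim$counts$counts) - lam) < 4 * se))
  expect_true(all(sim$log_rates == rep(dec$f, each = 2000)))
})

test_that("simulation reproduces the generative moments and is deterministic", {
  b <- build_benchmark("gain", B = 2000, seed = 11)
  # sample variance of the true gain scores near sigma1^2 = 1.25
  v <- var(b$scores[, 1])
  se <- 1.25 * sqrt(2 / 1999)
  expect_lt(abs(v - 1.25), 3 * se)
  # log-rate mean and variance match f and diag(Sigma)
  Sig <- 1.25 * tcrossprod(b$truth$phis[, 1]) + diag(b$truth$sigma0_2, 9)
  expect_true(all(abs(colMeans(b$log_rates) - b$truth$f) <
                    3 * sqrt(diag(Sig) / 2000)))
  expect_true(all(abs(apply(b$log_rates, 2, var) - diag(Sig)) <
                    3 * diag(Sig) * sqrt(2 / 1999)))
  # determinism: identical seed, bitwise-identical counts
  b2 <- build_benchmark("gain", B = 2000, seed = 11)
  expect_identical(b$counts$counts, b2$counts$counts)
})

test_that("latent fluctuations over-disperse the counts", {
  b <- build_benchmark("gain", B = 5000, seed = 3)
  x <- b$counts$counts
  ratio <- apply(x, 2, var) / colMeans(x)
  expect_true(all(ratio > 1))
})

test_that("simulation reports rate overflow with its location", {
  dec <- toy_decomp()
  dec$f[5] <- 50
  expect_error(simulate_counts(dec, B = 2, seed = 1),
               "overflow at block .*stimulus")
})

test_that("count and decomposition containers validate their invariants", {
  g <- benchmark_grid()
  expect_error(spike_count_matrix(matrix(-1, 2, 9), g), "non-negative")
  expect_error(spike_count_matrix(matrix(0.5, 2, 9), g), "non-negative integers")
  expect_error(stimulus_grid(c(1, 1, 2)), "strictly increasing")
  expect_error(tuning_decomposition(g, rep(0, 9), rep(1, 9), 1, 0),
               "unit Euclidean norm")
  expect_error(tuning_decomposition(g, rep(0, 9), cbind(rep(1/3, 9), rep(1/3, 9)),
                                    c(1, 1), 0), "orthogonal")
  expect_error(tuning_decomposition(g, rep(0, 9), rep(1/3, 9), 1, 0, dt = 0),
               "dt")
})
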