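#' Stimulus grid
#'
#' An ordered set of stimulus angles (in degrees) on which tuning curves,
#' fPCs and spike counts are defined.
#'
#' @param values Numeric vector of stimulus angles in degrees, strictly
#'   increasing.
#' @param periodic Logical; whether the grid samples a circular variable
#'   (e.g. orientation on 0--180 degrees). No wraparound is applied by the
#'   benchmark machinery; the flag is carried for circular-domain operations
#'   such as [shift_augment()].
#' @return An object of class `"stimulus_grid"`: a list with elements
#'   `values`, `spacing` (mean step, degrees) and `periodic`.
#' @examples
#' benchmark_grid()
#' @export
stimulus_grid <- function(values, periodic = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(diff(values) <= 0))
    stop("grid values must be strictly increasing with at least 2 points")
  structure(
    list(values = values, spacing = mean(diff(values)), periodic = isTRUE(periodic)),
    class = "stimulus_grid"
  )
}

#' @rdname stimulus_grid
#' @details `benchmark_grid()` returns the 9-point validation grid: -90 to 90
#'   degrees in steps of 22.5.
#' @export
benchmark_grid <- function() stimulus_grid(seq(-90, 90, by = 22.5))

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf("Stimulus grid: %d points, %.4g to %.4g deg (spacing %.4g)%s\n",
              length(x$values), min(x$values), max(x$values), x$spacing,
              if (x$periodic) ", periodic" else ""))
  invisible(x)
}

#' Bell-shaped benchmark tuning curve
#'
#' The mean tuning curve used throughout the simulation benchmarks:
#' a Gaussian bump of height 5 spikes/s over a 0.5 spikes/s baseline,
#' `mu0(s) = 0.5 + 5 * dnorm(s / 20) / dnorm(0)`.
#'
#' @param s Numeric vector of stimulus angles in degrees.
#' @return Firing rates (spikes/s), strictly positive and symmetric about 0.
#' @examples
#' benchmark_tuning_curve(0)   # 5.5
#' @export
benchmark_tuning_curve <- function(s) {
  0.5 + 5 * stats::dnorm(s / 20) / stats::dnorm(0)
}

#' Sigmoidal (monotonic) tuning curve
#'
#' A logistic mean tuning curve for validating the estimator on monotonic
#' tuning, matched in range to [benchmark_tuning_curve()].
#'
#' @param s Stimulus angles in degrees.
#' @param baseline,amplitude Baseline and dynamic range (spikes/s).
#' @param midpoint,slope Location and scale (degrees) of the logistic.
#' @return Firing rates (spikes/s), monotone non-decreasing in `s`.
#' @export
sigmoid_tuning_curve <- function(s, baseline = 0.5, amplitude = 5,
                                 midpoint = 0, slope = 20) {
  baseline + amplitude / (1 + exp(-(s - midpoint) / slope))
}

#' Reverse-engineered fluctuation fPC for a canonical tuning change
#'
#' Constructs the unit-norm functional principal component that, acting on the
#' log tuning curve, produces one of the four canonical types of tuning
#' fluctuation. Each direction is the difference of two log tuning curves:
#' \describe{
#'   \item{gain}{`log(1.3 mu0) - log(0.9 mu0)` -- constant in `s`
#'     (multiplicative gain).}
#'   \item{additive}{`log(mu0 + 0.4) - log(mu0 - 0.2)` -- requires
#'     `mu0 > 0.2` everywhere.}
#'   \item{shift}{`log(mu0(s + 6)) - log(mu0(s - 6))` -- lateral shift,
#'     evaluated analytically from the tuning-curve function.}
#'   \item{sharpen}{log of the +/-20% width-changed curves' difference,
#'     `log(mu0(s / 1.2)) - log(mu0(s / 0.8))`.}
#' }
#' The difference vector is divided by its Euclidean norm on the grid.
#'
#' @param kind One of `"gain"`, `"additive"`, `"shift"`, `"sharpen"`.
#' @param tuning Tuning-curve function of angle in degrees (default
#'   [benchmark_tuning_curve()]); must be strictly positive.
#' @param grid A [stimulus_grid()].
#' @return Unit-norm numeric vector over `grid$values`.
#' @examples
#' phi <- fluctuation_fpc("gain", grid = benchmark_grid())
#' all.equal(phi, rep(1 / 3, 9))
#' @export
fluctuation_fpc <- function(kind = c("gain", "additive", "shift", "sharpen"),
                            tuning = benchmark_tuning_curve,
                            grid = benchmark_grid()) {
  kind <- match.arg(kind)
  s <- grid$values
  mu0 <- tuning(s)
  .check_pos <- function(x, what) {
    if (any(x <= 0)) {
      bad <- s[which(x <= 0)[1L]]
      stop(sprintf("non-positive argument to log for %s at stimulus %.4g deg",
                   what, bad))
    }
    x
  }
  .check_pos(mu0, "the tuning curve")
  d <- switch(kind,
    gain = log(1.3 * mu0) - log(0.9 * mu0),
    additive = log(.check_pos(mu0 + 0.4, "mu0 + 0.4")) -
      log(.check_pos(mu0 - 0.2, "mu0 - 0.2")),
    shift = log(.check_pos(tuning(s + 6), "the shifted tuning curve")) -
      log(.check_pos(tuning(s - 6), "the shifted tuning curve")),
    sharpen = log(.check_pos(tuning(s / 1.2), "the widened tuning curve")) -
      log(.check_pos(tuning(s / 0.8), "the narrowed tuning curve"))
  )
  d / sqrt(sum(d^2))
}

#' Structured-plus-white covariance of log-rate fluctuations
#'
#' Builds `Sigma = sigma1_2 * phi phi' + c I`, with `c` solved so that the
#' structured (rank-one) component explains a stated share of the total
#' variance: `sigma1_2 / (sigma1_2 + m * c) = structured_share`.
#'
#' @param phi Unit-norm fPC direction (length `m`).
#' @param sigma1_2 Variance of the structured score (> 0).
#' @param structured_share Fraction of total variance carried by the
#'   structured component, in (0, 1). The benchmarks use 0.8.
#' @return A list with `Sigma` (m x m), `c` (white-noise variance), and
#'   `share` (the realized structured share, recomputed from the matrix).
#' @examples
#' sc <- structured_covariance(rep(1 / 3, 9), 1.25, 0.8)
#' sc$c  # 1.25 / 36
#' @export
structured_covariance <- function(phi, sigma1_2, structured_share) {
  if (abs(sum(phi^2) - 1) > 1e-8) stop("phi must have unit Euclidean norm")
  if (sigma1_2 <= 0) stop("sigma1_2 must be positive")
  if (structured_share <= 0 || structured_share >= 1)
    stop("structured_share must lie strictly between 0 and 1")
  m <- length(phi)
  cc <- sigma1_2 * (1 - structured_share) / (structured_share * m)
  Sigma <- sigma1_2 * tcrossprod(phi) + diag(cc, m)
  list(Sigma = Sigma, c = cc,
       share = sigma1_2 / (sigma1_2 + m * cc))
}

#' Tuning-curve decomposition
#'
#' The generative model of moment-to-moment tuning variability: the log
#' tuning curve at moment `t` is
#' `log mu_t(s) = f(s) + sum_k alpha_{k,t} phi_k(s) + eps_t(s)`,
#' with scores `alpha_{k,t} ~ N(0, sigma_k2[k])` and i.i.d. residual noise
#' `eps ~ N(0, sigma0_2)`; spike counts are Poisson with mean `mu_t(s) * dt`.
#'
#' @param grid A [stimulus_grid()].
#' @param f Mean log tuning curve over the grid (log spikes/s).
#' @param phis m x K matrix (or length-m vector) of unit-norm, mutually
#'   orthogonal fPCs.
#' @param sigma_k2 K non-negative score variances, non-increasing.
#' @param sigma0_2 Non-negative residual variance.
#' @param dt Counting-window length in seconds (> 0).
#' @return An object of class `"tuning_decomposition"`.
#' @export
tuning_decomposition <- function(grid, f, phis, sigma_k2, sigma0_2 = 0, dt = 1) {
  stopifnot(inherits(grid, "stimulus_grid"))
  phis <- as.matrix(phis)
  m <- length(grid$values)
  if (length(f) != m || nrow(phis) != m)
    stop("f and phis must be defined on the grid")
  K <- ncol(phis)
  if (length(sigma_k2) != K) stop("need one variance per component")
  if (any(sigma_k2 < 0) || sigma0_2 < 0) stop("variances must be non-negative")
  if (is.unsorted(rev(sigma_k2))) stop("sigma_k2 must be non-increasing")
  if (dt <= 0) stop("dt must be positive")
  nrm <- sqrt(colSums(phis^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("each fPC must have unit Euclidean norm")
  if (K > 1) {
    g <- crossprod(phis)
    if (max(abs(g[upper.tri(g)])) > 1e-6) stop("fPCs must be orthogonal")
  }
  structure(
    list(grid = grid, f = as.numeric(f), phis = phis,
         sigma_k2 = as.numeric(sigma_k2), sigma0_2 = sigma0_2, dt = dt),
    class = "tuning_decomposition"
  )
}

#' @export
print.tuning_decomposition <- function(x, ...) {
  cat(sprintf(
    "Tuning decomposition: %d grid points, %d fPC(s), dt = %g s\n",
    length(x$grid$values), ncol(x$phis), x$dt))
  cat("  score variances:", paste(signif(x$sigma_k2, 4), collapse = ", "),
      "| residual:", signif(x$sigma0_2, 4), "\n")
  invisible(x)
}

#' Spike-count matrix for one neuron
#'
#' @param counts B x m matrix of non-negative integer spike counts; one row
#'   per moment (block), columns aligned with `grid$values`.
#' @param grid A [stimulus_grid()].
#' @param dt Counting-window length in seconds.
#' @return Object of class `"spike_count_matrix"` with fields `counts`,
#'   `grid`, `dt`, `B`, `m`.
#' @export
spike_count_matrix <- function(counts, grid, dt = 1) {
  counts <- as.matrix(counts)
  stopifnot(inherits(grid, "stimulus_grid"))
  if (ncol(counts) != length(grid$values))
    stop("count columns must align with the stimulus grid")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (dt <= 0) stop("dt must be positive")
  storage.mode(counts) <- "double"
  colnames(counts) <- grid$values
  structure(list(counts = counts, grid = grid, dt = dt,
                 B = nrow(counts), m = ncol(counts)),
            class = "spike_count_matrix")
}

#' @export
print.spike_count_matrix <- function(x, ...) {
  cat(sprintf("Spike counts: %d blocks x %d stimuli, dt = %g s, mean %.2f\n",
              x$B, x$m, x$dt, mean(x$counts)))
  invisible(x)
}

#' Simulate spike counts from a tuning decomposition
#'
#' Draws, for each of `B` moments, Gaussian scores and residual noise, forms
#' the log rates `f + phis %*% alpha + eps`, and samples Poisson counts with
#' mean `exp(log mu) * dt`. The latent truths are returned for recovery
#' testing.
#'
#' @param decomp A [tuning_decomposition()].
#' @param B Number of moments (blocks), >= 1.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return List with `counts` (a [spike_count_matrix()]), `scores`
#'   (B x K matrix of true scores) and `log_rates` (B x m matrix).
#' @export
simulate_counts <- function(decomp, B, seed = NULL) {
  stopifnot(inherits(decomp, "tuning_decomposition"), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(decomp$f)
  K <- ncol(decomp$phis)
  alpha <- matrix(stats::rnorm(B * K), B, K) %*%
    diag(sqrt(decomp$sigma_k2), K)
  eps <- if (decomp$sigma0_2 > 0)
    matrix(stats::rnorm(B * m, sd = sqrt(decomp$sigma0_2)), B, m)
  else matrix(0, B, m)
  logmu <- matrix(decomp$f, B, m, byrow = TRUE) + alpha %*% t(decomp$phis) + eps
  lam <- exp(logmu) * decomp$dt
  if (any(!is.finite(lam)) || any(lam > 1e9)) {
    bad <- which(!is.finite(lam) | lam > 1e9, arr.ind = TRUE)[1L, ]
    stop(sprintf("rate overflow at block %d, stimulus %.4g deg",
                 bad[1L], decomp$grid$values[bad[2L]]))
  }
  counts <- matrix(stats::rpois(B * m, lam), B, m)
  list(counts = spike_count_matrix(counts, decomp$grid, decomp$dt),
       scores = alpha, log_rates = logmu)
}
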