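## Natural cubic-spline representations of a decomposition's smooth curves,
## for analytic derivatives.
.decomp_splines <- function(decomp) {
  s <- decomp$grid$values
  list(f = stats::splinefun(s, decomp$f, method = "natural"),
       phis = lapply(seq_len(ncol(decomp$phis)), function(k)
         stats::splinefun(s, decomp$phis[, k], method = "natural")))
}

.as_fi_decomp <- function(x) {
  if (inherits(x, "tuning_decomposition")) return(x)
  if (inherits(x, "pfpca")) {
    if (x$method != "pfpca")
      stop("Fisher information requires a log-rate (method = 'pfpca') fit")
    return(as_decomposition(x))
  }
  stop("expected a tuning_decomposition or pfpca fit")
}

#' Fisher information of one neuron at a stimulus
#'
#' Under the model, the tuning curve at scores `alpha` is
#' `mu(s) = exp(f(s) + sum_k alpha_k phi_k(s))` and the Poisson Fisher
#' information about the stimulus is
#' `I(s) = mu(s) * (f'(s) + sum_k alpha_k phi_k'(s))^2`.
#' Derivatives are taken analytically from natural cubic-spline
#' representations of the fitted smooth curves.
#'
#' @param decomp A [tuning_decomposition()] or a `method = "pfpca"` fit.
#' @param scores Length-K vector of component scores.
#' @param s Stimulus value(s) in degrees, within the grid range.
#' @return Non-negative Fisher information (spikes per squared degree,
#'   times the counting window when rates are per second).
#' @export
fisher_information <- function(decomp, scores, s) {
  decomp <- .as_fi_decomp(decomp)
  rng <- range(decomp$grid$values)
  if (any(s < rng[1L] | s > rng[2L]))
    stop("stimulus outside the grid range")
  K <- ncol(decomp$phis)
  stopifnot(length(scores) == K)
  sp <- .decomp_splines(decomp)
  g <- sp$f(s)
  d <- sp$f(s, deriv = 1L)
  for (k in seq_len(K)) {
    g <- g + scores[k] * sp$phis[[k]](s)
    d <- d + scores[k] * sp$phis[[k]](s, deriv = 1L)
  }
  exp(g) * d^2
}

#' Population Fisher information and activity per block
#'
#' Treating neurons as conditionally independent given the fluctuations,
#' sums each neuron's Fisher information over the stimulus grid and over
#' neurons, per block; population activity is the summed expected spike
#' count `mu(s) * dt` over the same grid and neurons.
#'
#' @param decomps List of per-neuron [tuning_decomposition()]s (or
#'   `method = "pfpca"` fits) on a common grid.
#' @param score_matrix Per-block scores: an `n_neurons x B` matrix (first
#'   component only) or an `n_neurons x B x K` array.
#' @param s Stimuli at which to evaluate (default: the first decomposition's
#'   grid).
#' @return Object of class `"fi_result"`: list with `fi` (per-block total
#'   Fisher information), `activity` (per-block total expected spike
#'   count), `per_neuron` (blocks x neurons matrix of summed FI) and
#'   `modulation_index` (see [fi_modulation_index()]; `NA` when undefined).
#' @export
population_fi <- function(decomps, score_matrix, s = NULL) {
  decomps <- lapply(decomps, .as_fi_decomp)
  n <- length(decomps)
  if (is.matrix(score_matrix))
    score_matrix <- array(score_matrix,
                          dim = c(dim(score_matrix), 1L))
  if (dim(score_matrix)[1L] != n)
    stop("score_matrix rows must match the number of neurons")
  B <- dim(score_matrix)[2L]
  Ks <- dim(score_matrix)[3L]
  if (is.null(s)) s <- decomps[[1L]]$grid$values
  per_neuron <- matrix(0, B, n)
  activity <- matrix(0, B, n)
  for (i in seq_len(n)) {
    dec <- decomps[[i]]
    K <- ncol(dec$phis)
    if (Ks > K) stop("more score components than fitted fPCs")
    sp <- .decomp_splines(dec)
    f0 <- sp$f(s)
    d0 <- sp$f(s, deriv = 1L)
    pv <- vapply(sp$phis[seq_len(Ks)], function(p) p(s), numeric(length(s)))
    dv <- vapply(sp$phis[seq_len(Ks)], function(p) p(s, deriv = 1L),
                 numeric(length(s)))
    for (t in seq_len(B)) {
      a <- score_matrix[i, t, ]
      mu <- exp(f0 + as.numeric(pv %*% a))
      dd <- d0 + as.numeric(dv %*% a)
      per_neuron[t, i] <- sum(mu * dd^2)
      activity[t, i] <- sum(mu * dec$dt)
    }
  }
  fi <- rowSums(per_neuron)
  act <- rowSums(activity)
  idx <- tryCatch(fi_modulation_index(fi, act), error = function(e) NA_real_)
  structure(list(fi = fi, activity = act, per_neuron = per_neuron,
                 modulation_index = idx),
            class = "fi_result")
}

#' @export
print.fi_result <- function(x, ...) {
  cat(sprintf("Population FI over %d blocks: mean %.4g (activity mean %.4g)\n",
              length(x$fi), mean(x$fi), mean(x$activity)))
  cat(sprintf("FI-modulation index: %.4g\n", x$modulation_index))
  invisible(x)
}

#' FI-modulation index
#'
#' The slope of the Fisher-information-versus-activity relation across
#' blocks, after dividing both series by their across-block means so that
#' an exactly proportional relation (pure multiplicative gain) yields a
#' slope of exactly 1.
#'
#' @param fi Per-block population Fisher information (length >= 3).
#' @param activity Per-block population activity; must not be constant.
#' @return The OLS slope of mean-normalized FI on mean-normalized activity.
#' @export
fi_modulation_index <- function(fi, activity) {
  if (length(fi) < 3L || length(fi) != length(activity))
    stop("need at least 3 aligned blocks")
  if (stats::var(activity) == 0)
    stop("activity is constant across blocks: slope undefined")
  y <- fi / mean(fi)
  x <- activity / mean(activity)
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Simulate-and-refit recovery of the FI-activity relation
#'
#' Generates a rank-1 multiplicative-gain population from known tuning
#' decompositions, refits every neuron with the full estimator, and
#' recomputes the population Fisher information and modulation index from
#' the fits, to check that the estimation pipeline preserves the
#' FI-activity relation (analytically, slope 1 for multiplicative gain).
#'
#' @param n_neurons Number of neurons.
#' @param B Number of blocks.
#' @param score_sd Per-neuron score standard deviation of the shared gain.
#' @param seed Integer seed (drives both simulation and the per-neuron EM).
#' @param em,fpca Controls passed to [pfpca()].
#' @param K Components per neuron fit.
#' @return List with `true_index`, `recovered_index`,
#'   `activity_correlation` and `fi_correlation` between true and recovered
#'   per-block values, plus the underlying `truth` and `fits`.
#' @export
fi_recovery_experiment <- function(n_neurons = 30, B = 200,
                                   score_sd = sqrt(1.25), seed = 1,
                                   em = em_control(M = 2000, max_iter = 30),
                                   fpca = fpca_control(),
                                   K = 1) {
  pop <- build_rank1_population(n_neurons, score_sd, "multiplicative",
                                B = B, seed = seed)
  true_scores <- pop$scores
  truth_fi <- population_fi(pop$truth, true_scores)
  fits <- lapply(seq_len(n_neurons), function(i) {
    emi <- em
    emi$seed <- seed + i
    pfpca(pop$counts[[i]], K = K, em = emi, fpca = fpca)
  })
  rec_scores <- t(vapply(fits, function(f) f$scores[, 1L], numeric(B)))
  rec_fi <- population_fi(fits, rec_scores)
  list(true_index = truth_fi$modulation_index,
       recovered_index = rec_fi$modulation_index,
       activity_correlation = stats::cor(truth_fi$activity, rec_fi$activity),
       fi_correlation = stats::cor(truth_fi$fi, rec_fi$fi),
       truth = truth_fi, fits = fits, recovered = rec_fi)
}
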