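#' Correlation structure of first-fPC scores across a population
#'
#' Pearson correlations between neurons' per-block score series, with a
#' display ordering from average-linkage hierarchical clustering on the
#' `1 - r` distance (the standard heat-map leaf ordering). Neurons with zero
#' score variance are excluded with a warning.
#'
#' @param scores `n_neurons x B` matrix of first-fPC scores.
#' @return List with `correlation` (n x n), `order` (leaf ordering of the
#'   retained neurons), `hclust` (the dendrogram object) and `kept` (indices
#'   of retained neurons).
#' @export
score_correlation <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 neurons")
  v <- apply(scores, 1L, stats::var)
  kept <- which(v > 0)
  if (length(kept) < nrow(scores))
    warning(sprintf("excluding %d zero-variance neuron(s)",
                    nrow(scores) - length(kept)))
  R <- stats::cor(t(scores[kept, , drop = FALSE]))
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(correlation = R, order = hc$order, hclust = hc, kept = kept)
}

#' Linear dimensionality of the population score matrix
#'
#' Eigen-spectrum of the across-neuron covariance of per-block scores,
#' normalized to variance shares. By default each neuron's score series is
#' z-scored first so that neurons with large score variance do not dominate
#' the spectrum.
#'
#' @param scores `n_neurons x B` matrix of scores.
#' @param standardize Z-score each neuron's series first (default `TRUE`).
#' @return List with `eigenvalues` (non-increasing) and `shares` (summing
#'   to 1).
#' @export
score_dimensionality <- function(scores, standardize = TRUE) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L || ncol(scores) < 2L)
    stop("need at least 2 neurons and 2 blocks")
  X <- t(scores)
  if (standardize) X <- scale(X)
  ev <- pmax(eigen(stats::cov(X), symmetric = TRUE,
                   only.values = TRUE)$values, 0)
  list(eigenvalues = ev, shares = ev / sum(ev))
}
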