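#' Population code over stimulus/condition states
#'
#' A states x neurons matrix of expected firing rates, where each state is
#' an (orientation, condition) pair, plus the orientation grid. The
#' container for representational-geometry analyses.
#'
#' @param rates States x neurons matrix of non-negative expected rates.
#' @param orientation Orientation label (degrees) of each state.
#' @param condition Condition label of each state (e.g. gain level or
#'   characteristic-state index).
#' @param orientations The circular orientation grid (degrees on
#'   `[0, 180)`) underlying the states, used by [shift_augment()].
#' @return Object of class `"population_code"`.
#' @export
population_code <- function(rates, orientation, condition,
                            orientations = sort(unique(orientation))) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (length(orientation) != nrow(rates) ||
      length(condition) != nrow(rates))
    stop("one orientation and condition label per state is required")
  structure(list(rates = rates,
                 states = data.frame(orientation = orientation,
                                     condition = condition),
                 orientations = orientations),
            class = "population_code")
}

#' @export
print.population_code <- function(x, ...) {
  cat(sprintf("Population code: %d states x %d neurons (%d orientations x %d conditions)\n",
              nrow(x$rates), ncol(x$rates), length(x$orientations),
              length(unique(x$states$condition))))
  invisible(x)
}

#' Homogeneous von Mises population under multiplicative gain
#'
#' A homogeneous orientation code: `n_neurons` von Mises tuning curves
#' (width parameter `kappa`) with preferred orientations equispaced on 180
#' degrees, each state being an (orientation bin, gain level) pair with
#' rates `gain * exp(kappa * cos(2 * (orientation - pref) * pi / 180))`.
#' The defaults give `180 x 4 = 720` states.
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param kappa Von Mises width parameter (default 1).
#' @param gains Multiplicative gain levels (default `c(0.25, 0.5, 0.75, 1)`).
#' @param n_orient Number of orientation bins on `[0, 180)` (default 180).
#' @return A [population_code()] with `n_orient * length(gains)` states.
#' @export
vonmises_population <- function(n_neurons = 60, kappa = 1,
                                gains = c(0.25, 0.5, 0.75, 1),
                                n_orient = 180) {
  stopifnot(n_neurons >= 2, n_orient >= 2, all(gains > 0))
  orient <- seq(0, 180, length.out = n_orient + 1L)[seq_len(n_orient)]
  prefs <- seq(0, 180, length.out = n_neurons + 1L)[seq_len(n_neurons)]
  tc <- exp(kappa * cos(2 * outer(orient, prefs, "-") * pi / 180))
  rates <- do.call(rbind, lapply(gains, function(g) g * tc))
  population_code(rates,
                  orientation = rep(orient, length(gains)),
                  condition = rep(gains, each = n_orient),
                  orientations = orient)
}

#' Representational distance matrix
#'
#' Pairwise Euclidean distances between the states' population response
#' vectors, optionally after the square-root variance-stabilizing transform
#' for Poisson noise.
#'
#' @param code A [population_code()].
#' @param transform `"none"` (raw rates) or `"sqrt"`.
#' @return A symmetric states x states distance matrix with zero diagonal.
#' @export
representational_distance <- function(code, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  R <- code$rates
  if (transform == "sqrt") R <- sqrt(R)
  as.matrix(stats::dist(R))
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centering eigendecomposition ([stats::cmdscale()]). If fewer than
#' `d` positive eigenvalues exist, the remaining coordinates are zero-padded
#' with a warning.
#'
#' @param distances Symmetric distance matrix.
#' @param d Embedding dimension (>= 1).
#' @return List with `points` (states x d, centered at the origin) and
#'   `eig` (the full eigenvalue spectrum, non-increasing).
#' @export
classical_mds <- function(distances, d = 3) {
  stopifnot(d >= 1)
  mds <- stats::cmdscale(distances, k = d, eig = TRUE)
  pts <- mds$points
  npos <- sum(mds$eig > max(mds$eig) * 1e-8)
  if (ncol(pts) < d || npos < d) {
    warning(sprintf("only %d positive eigenvalue(s); padding to %d dimensions with zeros",
                    min(ncol(pts), npos), d))
    if (ncol(pts) < d) pts <- cbind(pts, matrix(0, nrow(pts), d - ncol(pts)))
    if (npos < d) pts[, (npos + 1L):d] <- 0
  }
  list(points = pts, eig = mds$eig)
}

#' Characteristic population states by k-means clustering of scores
#'
#' Clusters the blocks of a neurons x blocks score matrix into `k` groups
#' (k-means over blocks with multiple restarts) and returns each cluster's
#' mean score vector, ordered by increasing total mean score, yielding `k`
#' characteristic fluctuation states of the population.
#'
#' @param scores `n_neurons x B` score matrix.
#' @param k Number of states (default 10); requires `B >= k`.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (default 10).
#' @return List with `states` (`k x n_neurons` matrix of cluster-mean
#'   scores), `cluster` (block assignments) and `sizes`.
#' @export
characteristic_states <- function(scores, k = 10, seed = 1, nstart = 10) {
  scores <- as.matrix(scores)
  B <- ncol(scores)
  if (B < k) stop("need at least as many blocks as states")
  X <- t(scores)
  set.seed(seed)
  km <- if (k == 1L)
    list(centers = matrix(colMeans(X), 1L), cluster = rep(1L, B),
         size = B)
  else stats::kmeans(X, centers = k, nstart = nstart)
  o <- order(rowSums(km$centers))
  states <- km$centers[o, , drop = FALSE]
  relab <- match(seq_len(k), o)
  list(states = unname(states), cluster = relab[km$cluster],
       sizes = as.integer(table(factor(relab[km$cluster], levels = seq_len(k)))))
}

#' Augment a population code with shifted tuning-curve copies
#'
#' Makes the code more shift-invariant by adding, for every neuron,
#' `n_shifts` copies whose tuning curves are rotated by multiples of `step`
#' degrees on the circular 180-degree orientation domain. A copy shifted by
#' `delta` responds at orientation `o` as the original did at
#' `(o - delta) mod 180`.
#'
#' @param code A [population_code()] whose orientation grid covers
#'   `[0, 180)` with a spacing that divides `step`.
#' @param n_shifts Number of shifted copies (default 8).
#' @param step Shift per copy in degrees (default 20).
#' @return A [population_code()] with `(n_shifts + 1) * n_neurons` neurons.
#' @export
shift_augment <- function(code, n_shifts = 8, step = 20) {
  stopifnot(inherits(code, "population_code"))
  orient <- code$orientations
  n_or <- length(orient)
  spacing <- 180 / n_or
  if (max(abs(diff(orient) - spacing)) > 1e-8 ||
      abs(orient[1L]) > 1e-8)
    stop("shift augmentation requires an equispaced circular grid on [0, 180)")
  shift_bins <- step / spacing
  if (abs(shift_bins - round(shift_bins)) > 1e-8)
    stop("shift step must be a multiple of the orientation spacing")
  shift_bins <- as.integer(round(shift_bins))
  cond <- code$states$condition
  ostate <- code$states$orientation
  obin <- match(round(ostate, 8), round(orient, 8))
  if (anyNA(obin)) stop("state orientations must lie on the orientation grid")
  blocks <- lapply(0:n_shifts, function(j) {
    if (j == 0L) return(code$rates)
    src_bin <- ((obin - 1L - j * shift_bins) %% n_or) + 1L
    # row for state (o, cond) reads the original row at (o - delta, cond)
    key <- paste(src_bin, cond)
    idx <- match(key, paste(obin, cond))
    code$rates[idx, , drop = FALSE]
  })
  population_code(do.call(cbind, blocks), ostate, cond, orient)
}

#' Radius of a state group in an embedding
#'
#' Mean distance of a group of embedded states from the group centroid in
#' the first two embedding dimensions -- the ring radius used to quantify
#' how representation size scales with activity.
#'
#' @param embedding States x d coordinate matrix (from [classical_mds()]).
#' @param state_group Indices (or logical mask) of the states in the group,
#'   at least 3.
#' @return Non-negative scalar radius (0, with a warning, for a degenerate
#'   group).
#' @export
representation_radius <- function(embedding, state_group) {
  pts <- embedding[state_group, 1:2, drop = FALSE]
  if (nrow(pts) < 3L) stop("state group must contain at least 3 states")
  ctr <- colMeans(pts)
  r <- mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
  if (r == 0) warning("degenerate state group: zero radius")
  r
}
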