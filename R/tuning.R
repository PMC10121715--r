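#' Regress the first fPC on the mean component
#'
#' Ordinary least squares of `phi1(s) = b + w f(s) + e(s)` over the grid
#' points, with the F-test p-value of the regression and the fraction index
#' `1 - sum(e^2) / sum(phi1^2)`, the share of the first fPC accounted for by
#' a linear function of the mean component.
#'
#' @param phi1 First fPC over the grid (length >= 3).
#' @param f Mean component over the grid; must not be constant.
#' @return Object of class `"powerlaw_fit"`: list with `b` (intercept), `w`
#'   (slope), `residuals`, `p_value` and `fraction`.
#' @export
regress_fpc_on_mean <- function(phi1, f) {
  if (length(phi1) != length(f) || length(f) < 3L)
    stop("phi1 and f must have equal length >= 3")
  if (stats::var(f) == 0) stop("mean component is constant: degenerate regressor")
  fit <- stats::lm(phi1 ~ f)
  fs <- suppressWarnings(summary(fit))$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  e <- stats::residuals(fit)
  structure(
    list(b = unname(stats::coef(fit)[1L]), w = unname(stats::coef(fit)[2L]),
         residuals = unname(e), p_value = p,
         fraction = 1 - sum(e^2) / sum(phi1^2)),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("phi1 = b + w f: b = %.4g, w = %.4g (p = %.3g), fraction = %.3f\n",
              x$b, x$w, x$p_value, x$fraction))
  invisible(x)
}

#' Power-law tuning modulation
#'
#' The unifying modulation form `mu_t(s) = mu0(s)^(1 + w * alpha) *
#' exp(b * alpha)`: with `w = 0` it is a pure multiplicative gain, and for
#' suitable `(b, w)` it approximates an additive rate change.
#'
#' @param mu0 Baseline tuning curve (> 0).
#' @param b,w Intercept and slope of the power-law relation.
#' @param alpha Score (fluctuation amplitude).
#' @return Modulated rates, elementwise `mu0^(1 + w * alpha) * exp(b * alpha)`.
#' @export
powerlaw_tuning <- function(mu0, b, w, alpha) {
  if (any(mu0 <= 0)) stop("mu0 must be strictly positive")
  mu0^(1 + w * alpha) * exp(b * alpha)
}

#' Von Mises tuning curve normalized to a fixed range
#'
#' Orientation tuning (180-degree periodic) used by the flatness analysis:
#' a von Mises bump rescaled so its minimum equals `baseline` and its
#' maximum equals `peak` exactly.
#'
#' @param s Orientation(s) in degrees.
#' @param baseline,peak Minimum and maximum rate (`0 < baseline < peak`).
#' @param kappa Width parameter of the von Mises (default 1).
#' @param pref Preferred orientation in degrees.
#' @return Rates in `[baseline, peak]`.
#' @export
vonmises_tuning <- function(s, baseline = 0.2, peak = 1, kappa = 1,
                            pref = 90) {
  if (baseline <= 0 || baseline >= peak)
    stop("need 0 < baseline < peak")
  vm <- exp(kappa * cos(2 * (s - pref) * pi / 180))
  lo <- exp(-kappa)
  hi <- exp(kappa)
  baseline + (peak - baseline) * (vm - lo) / (hi - lo)
}

#' Flatness-analysis settings
#'
#' @param baseline Baseline `c` of the von Mises tuning curve (default 0.2).
#' @param peak Peak rate (default 1).
#' @param kappa Von Mises width parameter (default 1).
#' @param pref Preferred orientation in degrees (default 90; the orthogonal
#'   orientation is 90 degrees away).
#' @param alpha_eval Score at which [flatness_map()] evaluates the index
#'   (default 1: one score standard deviation in normalized units).
#' @return List of class `"flatness_control"`.
#' @export
flatness_control <- function(baseline = 0.2, peak = 1, kappa = 1, pref = 90,
                             alpha_eval = 1) {
  if (baseline <= 0 || baseline >= peak) stop("need 0 < baseline < peak")
  structure(list(baseline = baseline, peak = peak, kappa = kappa,
                 pref = pref, alpha_eval = alpha_eval),
            class = "flatness_control")
}

#' Flatness index of a tuning modulation
#'
#' Quantifies how stimulus-dependent a firing-rate change is. With the von
#' Mises baseline curve `mu0` (range `[c, peak]`), the modulated curve
#' `mu_alpha`, and the corrected change
#' `Delta_mu(s) = mu_alpha(s) - mu0(s) - c * (exp(b * alpha) - 1)`,
#' the index is `Delta_mu(s_orth) / Delta_mu(s_pref)`. Pure multiplicative
#' gain gives 0, an explicit additive change gives 1, and negative values
#' indicate sharpening.
#'
#' By default the modulation is the power law
#' [powerlaw_tuning()]`(mu0, b, w, alpha)`; alternatively pass `mu_alpha`, a
#' function of orientation, for non-power-law modulations (e.g. the explicit
#' additive case `function(s) mu0(s) + c_add * alpha`), in which case `b`
#' only enters the correction term (default 0).
#'
#' @param b,w Power-law intercept and slope.
#' @param alpha Score at which the modulation is evaluated.
#' @param control A [flatness_control()].
#' @param mu_alpha Optional modulated tuning curve as a function of
#'   orientation (overrides the power law).
#' @return The flatness index (scalar).
#' @examples
#' flatness_index(b = 0.3, w = 0, alpha = 1)   # multiplicative: 0
#' @export
flatness_index <- function(b = 0, w = 0, alpha = 1,
                           control = flatness_control(), mu_alpha = NULL) {
  mu0 <- function(s) vonmises_tuning(s, control$baseline, control$peak,
                                     control$kappa, control$pref)
  if (is.null(mu_alpha))
    mu_alpha <- function(s) powerlaw_tuning(mu0(s), b, w, alpha)
  # written as c*e - c (not c*(e - 1)) so the multiplicative case cancels
  # exactly in floating point at the orthogonal orientation
  corr <- control$baseline * exp(b * alpha) - control$baseline
  dmu <- function(s) mu_alpha(s) - mu0(s) - corr
  s_pref <- control$pref
  s_orth <- control$pref + 90
  denom <- dmu(s_pref)
  if (abs(denom) < 1e-14)
    stop("flatness undefined: no rate change at the preferred orientation")
  dmu(s_orth) / denom
}

#' Flatness index over a grid of power-law parameters
#'
#' Evaluates [flatness_index()] on the Cartesian product of intercepts and
#' slopes at score `control$alpha_eval`; parameter combinations where the
#' index is undefined yield `NA` rather than an error.
#'
#' @param b_grid,w_grid Numeric vectors of intercepts and slopes.
#' @param control A [flatness_control()].
#' @return Matrix of flatness values, rows indexed by `b_grid`, columns by
#'   `w_grid`.
#' @export
flatness_map <- function(b_grid, w_grid, control = flatness_control()) {
  stopifnot(all(is.finite(b_grid)), all(is.finite(w_grid)))
  out <- outer(seq_along(b_grid), seq_along(w_grid),
               Vectorize(function(i, j) {
                 tryCatch(flatness_index(b_grid[i], w_grid[j],
                                         control$alpha_eval, control),
                          error = function(e) NA_real_)
               }))
  dimnames(out) <- list(b = signif(b_grid, 6), w = signif(w_grid, 6))
  out
}
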