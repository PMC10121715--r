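# pfpca: Poisson functional PCA of neural tuning variability

Neural tuning curves — a neuron's mean firing rate as a function of a
stimulus variable such as visual orientation — fluctuate from moment to
moment with latent brain state. Classic analyses presuppose the *form* of
that fluctuation (a multiplicative gain, an additive offset, a peak
shift); this package estimates the form directly from spike counts, for
anyone analyzing blocked tuning-curve recordings (e.g. primary visual
cortex under repeated stimulus sets) who wants to know *how* tuning
varies, not just that it does.

## The model

For moment (block) *t* and stimulus *s* on a grid of *m* values, the log
tuning curve is decomposed as

    log mu_t(s) = f(s) + sum_k alpha_{k,t} phi_k(s) + eps_t(s)

with smooth mean `f`, smooth orthonormal functional principal components
(fPCs) `phi_k`, Gaussian scores `alpha_{k,t} ~ N(0, sigma_k^2)`,
residual noise `eps ~ N(0, sigma_0^2)`, and Poisson spike counts
`n_t(s) ~ Poisson(mu_t(s) * dt)`. A constant `phi_1` is multiplicative
gain; other shapes capture additive, shift and width changes — all
estimated, not assumed.

Fitting is a two-step procedure:

1. **Monte-Carlo EM** recovers the posterior of the latent log rates,
   `E[log mu_t | n_t]` and `Cov[log mu_t | n_t]`, by self-normalized
   importance sampling under the current Gaussian prior `N(f, Sigma)`.
2. **Penalized functional PCA** of the posterior means extracts `f` (a
   natural cubic smoothing spline, GCV penalty), the fPCs (penalized
   Rayleigh quotient with a roughness penalty on `phi''`), per-moment
   scores and variance shares.

Comparators `method = "pca"` (ordinary PCA of raw counts) and
`method = "mupca"` (ordinary PCA of exponentiated posterior means) share
the same interface. Downstream analyses cover the power-law modulation
model `mu_t(s) = mu0(s)^(1 + w alpha) exp(b alpha)` and its flatness
index, Fisher information of the population code, population score
structure, and representational geometry via classical MDS.

## Worked example

Simulate the calibrated multiplicative-gain benchmark (bell-shaped tuning
curve on the 9-point grid from −90° to 90°, 50 blocks, the structured
component explaining 80% of log-rate variance) and fit the model:

```r
library(pfpca)

bench <- build_benchmark("gain", seed = 1)
fit <- pfpca(bench$counts, K = 3, em = em_control(M = 10000, seed = 2))
summary(fit)
#> Method: pfpca | 50 blocks, 9 stimuli, K = 3
#>                   fPC1    fPC2   fPC3
#> score variance  0.3691  0.1454 0.0197
#> share (%)      69.1000 27.2000 3.7000
#> Residual variance sigma0^2: 0.00323
#> EM: 30 iterations, mean E-step ESS 2969

regress_fpc_on_mean(fit$phis[, 1], fit$f)
#> phi1 = b + w f: b = 0.3011, w = 0.08575 (p = 0.0548), fraction = 0.937

score_recovery(fit$scores[, 1], fit$phis[, 1],
               bench$scores[, 1], bench$truth$phis[, 1])$correlation
#> [1] 0.757
```

The first fPC carries 69% of the recovered variance (the generator put
80% into it; the white-noise floor claims the rest across the remaining
components). Its regression on the mean component has slope near 0 and
fraction 0.94 — the signature of a near-constant component, i.e. the
multiplicative gain that generated the data. The per-moment scores
correlate 0.76 with the latent ground truth. `plot(fit)` draws the mean
tuning curve with the ±1 s.d. excursions of the first component;
`simulate(fit)` generates new datasets from the fitted decomposition.

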