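Package: pfpca
Title: Poisson Functional Principal Component Analysis of Neural Tuning Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decomposes moment-to-moment variability of neural tuning curves
    directly from spike counts. Fits a generative model in which the logarithm
    of a neuron's tuning curve fluctuates around a smooth mean along smooth
    functional principal components (fPCs) with Gaussian scores, observed
    through Poisson spiking. Estimation proceeds in two steps: a Monte-Carlo
    EM algorithm recovers the posterior of the latent log firing rates, then
    penalized functional PCA extracts the mean component, fPCs and per-moment
    scores. Includes comparator decompositions (PCA on counts, mu-PCA),
    calibrated synthetic-data generators for validation, and downstream
    analyses: power-law modulation and flatness index, Fisher information of
    the population code, population score structure, and representational
    geometry via classical multidimensional scaling.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
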