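Package: ca3metric
Title: Metric Resolution of Self-Organized CA3 Spatial Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a threshold-linear recurrent model of hippocampal area
    CA3 driven by sparse multi-field dentate-gyrus place units on a periodic
    (torus) environment, with trace-based Hebbian plasticity on the recurrent
    collaterals. Provides template-based maximum-likelihood Euclidean
    population decoding, full and translation-averaged (reduced) spatial
    confusion matrices, mutual-information and percent-correct analyses with
    closed-form information bounds and the metric content index, sigmoid fits
    of information versus sample size, Gaussian-bump fits of the reduced
    matrix, sigma-parameterized reference information curves (including a
    two-bump drift variant for input-free attractor dynamics), the metric
    resolution index chi = 1 - sigma/w, and Sammon multidimensional scaling
    of population templates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    minpack.lm,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
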