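Package: wormdyn
Title: Multi-Neuron Calcium Imaging Dynamics Metrics for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying age-associated breakdown of
    neuronal population dynamics in C. elegans calcium imaging recordings.
    Provides dF/F0 normalization, total-variation regularized differentiation,
    hyperbolic-tangent transition kinetics of bistable neurons, power spectral
    densities and spectral-edge frequencies, pairwise correlation structure of
    the most active neurons, PCA state-space trajectories with angular-change
    stochasticity metrics, global-quiescence bout detection, and a seeded
    synthetic-data generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    rhdf5,
    tibble,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
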