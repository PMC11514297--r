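Package: nmrtwist
Title: Pure-Absorption 2D NMR Spectra from Single Echo or Anti-Echo Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing of phase-modulated (Echo/Anti-Echo) two-dimensional
    NMR data beyond traditional quadrature detection. Provides hypercomplex
    States-equivalent spectral processing, the Virtual Echo transform with
    P/N quadrant projectors, compressed-sensing iterative soft-thresholding
    (IST) completion of single-quadrature and non-uniformly sampled data,
    Poisson-gap schedule generation, a trainable dilated-convolution
    reconstruction cascade with inter-stage data-consistency correction,
    per-point intensity uncertainty estimation by negative log-likelihood
    training, a reference-free spectrum quality score (pSQ), and
    reference-based quality metrics, together with a synthetic hypercomplex
    FID simulator for training and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
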