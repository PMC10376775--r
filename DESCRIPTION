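Package: maskaware
Title: Entropy and Integrated-Information Analysis of Auditory Perceptual
    Awareness Under Informational Masking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study the electrophysiological correlates of auditory
    perceptual awareness in informational-masking experiments: synthesis of
    random multi-tone maskers with an ERB-protected target region, session
    construction and signal-detection scoring (d-prime), a synthetic
    multichannel EEG generator with configurable ground-truth effects,
    zero-phase preprocessing and topographic cluster aggregation, tone-locked
    ERP peak extraction (awareness-related negativity and P300), five windowed
    entropy estimators (spectral, approximate, sample, permutation and
    singular-value decomposition entropy), four integrated-information
    measures on stationary Gaussian models (decoding-based, geometric,
    stochastic interaction and multi-information), mixed-effects inference
    with estimated-marginal-means contrasts, and a Monte-Carlo power
    calculator for random-intercept designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
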