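Package: bicoh
Title: Bispectral Cross-Frequency Coupling Analysis of Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Speed-binned spectral and higher-order spectral analysis of
    multi-channel local field potential (LFP) recordings. Implements Welch
    cross-spectra, auto- and cross-bispectra with the bicoherence
    normalization, principal-domain symmetries, Monte-Carlo null significance
    levels, region-of-interest coupling statistics for theta-theta harmonic
    and theta-gamma interactions, frequency-pair power correlograms,
    spike-train spectral analysis, and head-direction / theta-phase tuning
    statistics with cell classification. Includes readers for flat-binary
    LFP, spike index/cluster, and tracking file dialects, and a synthetic
    two-region LFP and spike generator with known, recoverable coupling
    parameters for estimator validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
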