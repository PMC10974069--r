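Package: gaplsr
Title: Genetic-Algorithm Wavelength Selection and PLSR for Indirect Soil
    Heavy-Metal Estimation from Leaf Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate soil cadmium and arsenic concentrations
    indirectly from crop-leaf reflectance spectra. Provides a calibrated
    synthetic cohort generator (stress-modulated vegetation spectra paired
    with correlated truncated log-normal metal concentrations), spectral
    pre-processing (band trimming, Savitzky-Golay smoothing, absorbance,
    first/second derivatives, multiplicative scatter correction, standard
    normal variate), NIPALS partial least squares regression with
    cross-validated component selection, genetic-algorithm wavelength
    selection with cross-validated RMSE as the fitness criterion, and
    RPD-based model evaluation on the Williams five-level scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
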