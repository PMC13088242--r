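Package: spiritspec
Title: Chemometric Screening of Distillate Fractions and Quality Analytes
    from ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native chemometrics pipeline for screening spirit
    distillates from attenuated-total-reflectance Fourier-transform infrared
    (ATR-FTIR) spectra. Provides a synthetic spectra generator for the three
    fractions of a batch distillation (head, body, tail) built from
    Beer-Lambert mixtures of component band profiles, Savitzky-Golay
    second-derivative preprocessing with region selection and vector-norm
    normalization, SIMCA class modeling with interclass distances and
    discriminating power, PLS1 regression with leave-one-out cross-validation,
    leverage/studentized-residual outlier diagnostics and external validation
    (RMSEP, correlation, residual predictive deviation), and an end-to-end
    workflow that reproduces the structure of a fraction-screening study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
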