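Package: remispeckle
Title: Rapid Quasi-Analytic Fitting of Multi-Exposure Speckle Contrast Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative blood-flow imaging with multi-exposure
    laser speckle contrast imaging (MESI). Implements closed-form speckle
    contrast models for mixed ordered/unordered multiple scattering, a
    reference per-pixel nonlinear least-squares fitter, a fast quasi-analytic
    estimator (REMI) based on the semilogarithmic derivative of squared
    contrast together with a spatially regularized variant (sREMI), a
    synthetic-data simulator with known ground truth, and a benchmark harness
    for comparing estimators in log-correlation-time space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
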