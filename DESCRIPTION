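Package: rootpheno
Title: Automated Root Trait Phenotyping from Two-Dimensional Scanned Images
Version: 0.1.0
Authors@R:
    person("rootpheno", "developers", email = "rootpheno@example.org",
           role = c("aut", "cre"))
Description: Segments scanned root images (dark roots on a light background)
    with automatic thresholding (Otsu, triangle, mean/Gaussian adaptive),
    thins the binary mask to a one-pixel skeleton, and estimates calibrated
    root traits: total root length, average diameter, surface area, root
    volume and projected area. Includes pixel-to-centimetre calibration from
    scanner DPI or a two-point ruler measurement, agreement statistics
    (RMSE, mean bias error, R squared) against reference measurements, and a
    synthetic wire-phantom generator with closed-form ground truth for
    validating the measurement chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    png,
    jpeg,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
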