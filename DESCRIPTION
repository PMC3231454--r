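Package: grapenir
Title: Vis-NIR Chemometrics for Grape Quality: MPLS and LOCAL Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting internal quality parameters of wine grapes
    (soluble solids, reducing sugars, pH, titratable acidity, tartaric and
    malic acid, potassium) from visible/near-infrared reflectance spectra
    collected during on-vine ripening. Implements standard normal variate
    plus detrend scatter correction, WinISI-style gap-segment derivative
    pretreatments, CENTER-style population structuring with Mahalanobis
    GH/NH statistics, PLS1 and modified PLS (MPLS) calibration with grouped
    cross-validation, the LOCAL memory-based regression algorithm with its
    k-by-l optimization grid, the full NIRS diagnostic-statistics suite
    (SEC, SECV, SEP, SEP(c), bias, RPD, CV%), and a synthetic grape-spectra
    generator for end-to-end testing of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
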