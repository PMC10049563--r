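Package: metalrisk
Title: Soil Heavy-Metal Pollution Indices, Risk Surfaces and Source
    Apportionment for Functional-Area Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment pipeline for heavy-metal concentrations (Zn, Cu,
    Cr, Pb, As, Hg) in georeferenced surface-soil samples from land-use
    functional areas. Computes the Muller geo-accumulation index, the
    single-factor pollution index and the Hakanson potential ecological
    risk index with their standard class schemes; per-area descriptive
    statistics with coefficient-of-variation screening and exceedance
    ratios against regional background values and GB 15618-2018 screening
    levels; inverse-distance-weighted concentration and risk surfaces
    with ESRI ASCII grid export; and a source-apportionment stage
    (Pearson correlation, KMO and Bartlett adequacy tests, correlation
    PCA with varimax rotation, hierarchical clustering of elements).
    Includes a calibrated Gaussian-copula generator that emulates the
    per-area marginal statistics and correlation structure of a
    semi-arid functional-area survey, so the whole pipeline runs and is
    testable without raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
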