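Package: echinodrill
Title: Drilling Predation Intensity on Fossil Echinoids Through Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cassid gastropod drilling predation on
    Mesozoic and Cenozoic echinoid populations. Builds stage-binned
    drilling-frequency time series with bootstrap sample standardization,
    fits two- and three-phase drilling-intensification models by Monte
    Carlo resampling of first differences scored by inverse sum of squared
    deviations, detects mean-shift changepoints in predator and prey
    diversity curves, and estimates partial correlations between drilling
    frequency and taphonomic covariates. Includes a seeded synthetic-data
    generator that emulates the structure of specimen- and population-level
    drill-hole compilations so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
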