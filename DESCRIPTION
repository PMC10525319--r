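Package: stemflux
Title: Daily and Seasonal Stem Radius Variation Analysis for Point-Dendrometer Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to process high-resolution (30-minute) point-dendrometer
    records of whole-stem and xylem radius together with co-located
    microclimate records. Corrects thermal-expansion artifacts, derives
    vapour pressure deficit, decomposes over-bark records into xylem and
    inner-bark components, reduces traces to daily metrics, removes seasonal
    trends with a Fourier low-pass filter, and quantifies xylem-phloem
    hydraulic coupling via rank correlations, stepwise regression,
    logarithmic amplitude-VPD fits and cross-correlation lag estimation.
    Includes a transpiration-driven two-compartment stem hydraulics
    simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
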