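Package: pwsfire
Title: Plant-Water Sensitivity and Wildfire Vulnerability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plant-water sensitivity (PWS) from gridded live and
    dead fuel moisture content time series via non-negative distributed-lag
    regression, links PWS to the sensitivity of burned area to vapour
    pressure deficit through equal-vegetated-area binning, attributes
    spatial PWS variability to plant and soil hydraulic traits with a
    random-forest ensemble, and quantifies double-hazard regions and
    wildland-urban-interface population exposure by hazard zone. Ships a
    synthetic gridded data generator with a recorded ground truth so the
    full pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
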