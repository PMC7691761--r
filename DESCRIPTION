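Package: tedzone
Title: Technology Extrapolation Domains for Scaling Out Agronomic Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates technology extrapolation domains (TEDs) -- zones with a
    unique combination of climate-zone class (growing degree-days, aridity
    index, temperature seasonality) and binned root-zone plant-available water
    holding capacity (PAWHC) -- and provides the downstream analyses that make
    the zonation useful for agronomic research planning: crop-area coverage
    curves and the trial-placement efficiency frontier, greedy maximum-coverage
    site selection, zone-level yield and yield-stability (inter-annual CV)
    evaluation with variance partitioning, and cross-region analog-zone
    comparison of cropping-system income and risk. Ships a synthetic-data
    generator for gridded weather, soil and yield panels so the whole pipeline
    runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
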