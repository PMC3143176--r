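Package: aedespop
Title: Container-Resolution Simulation and Spatial Analysis of Aedes
    aegypti Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stochastic, spatially explicit, daily-time-step simulator of
    Aedes aegypti populations resolved to individual water-holding
    containers within houses on a rectangular grid.  Food input into each
    container follows a multiplicative model (baseline rate, container-type
    coefficient, location coefficient, volume) that mediates larval density
    dependence through starvation and delayed development.  The package
    provides weather-series ingestion and synthesis for equatorial and
    temperate regimes, replicated-block grid construction from household
    container surveys, iterative calibration of the food coefficients
    against per-type pupal productivity or ovitrap-positivity targets,
    spatial autocorrelation statistics (Moran's I, weighted second-order L
    functions, local G with cluster labelling), and an end-to-end
    evaluation pipeline with synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
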