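Package: silicoag
Title: Coagulation-Fragmentation Kinetics of Silicification-Induced Cell Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of a truncated
    coagulation-fragmentation (Smoluchowski-type) reaction network describing
    the aggregation of surface-silicified bacteria after addition of a silica
    precursor. Provides the mass-conserving ODE right-hand side with a
    size-truncation logic gate, adaptive stiff integration, mapping of
    size-resolved trajectories to supernatant OD600 settlement observables, an
    exact Gillespie stochastic oracle for the same network, least-squares
    calibration of kinetic parameters from settlement time series, and a
    synthetic settlement-data generator emulating plate-reader measurement
    designs (5-minute sampling cadence, replicated density sweeps, endpoint
    normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
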