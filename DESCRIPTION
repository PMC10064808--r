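Package: pyrocosm
Title: Simulated Wildland Fire Heat Transfer and Soil Microbial Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing laboratory burn mesocosms ("pyrocosms") in
    which a calibrated torch heats a soil column to emulate wildland fire.
    Builds ramp-hold-decay surface forcing curves, solves one-dimensional
    heat conduction through the soil profile at 0.1 cm and 1 s resolution
    with a Crank-Nicolson scheme, reduces the simulated temperature field to
    depth-wise heat-exposure metrics and a microbial heat mortality zone,
    and runs the associated survival statistics: Welch t-test comparisons of
    thermocouple traces between cover types, chi-squared tests on
    colony-forming-unit presence/absence grids, and logistic recovery of a
    lethal-peak-temperature midpoint from depth-stratified culture data.
    Includes seeded synthetic-data generators for thermocouple traces and
    culture grids so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
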