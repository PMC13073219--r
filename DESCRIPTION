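Package: dualdispatch
Title: Simulation of EMS and Fire Service Dual-Dispatch Response Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of out-of-hospital cardiac arrest response
    times under EMS-only dispatch versus dual dispatch of EMS and volunteer
    fire services. Generates a synthetic study region (population-density
    raster, speed-classed road network, EMS and fire station sets), samples
    population-weighted arrest locations, computes fastest-route travel times
    on the network, converts them to response times with service-specific
    turnout times, and compares strategies with paired tests, a fire-turnout
    sensitivity sweep, and a density-by-strategy regression. Includes plain
    text exchange formats (CSV, ASCII grid, GeoJSON) and reporting with
    distribution plots and first-arriver maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
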