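Package: reservesim
Title: Bio-Economic Simulation of No-Take Marine Reserves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-structured bio-economic simulator of no-take marine
    reserves on a linear coastline. Couples Deriso-Schnute delay-difference
    biomass dynamics with Gaussian larval dispersal and adult movement,
    Beverton-Holt steepness recruitment, and an economic layer combining
    fishery profit with a linear-inverse-demand dive tourism model
    (revenue-maximising fees, consumer surplus, dive caps). Includes a
    scenario engine for reserve-implementation experiments, a demand
    calibration routine, a synthetic scenario generator for property-based
    testing, tidy accessors, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
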