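Package: mossmetrics
Title: Water Retention and 3D Colony Morphometry for Sphagnum Mosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies water-holding capacity and colony structure of
    Sphagnum mosses from three kinds of records: centrifugal
    water-fractionation ledgers (mass of water released at increasing
    centrifugal force), micro-CT voxel image stacks (plant volume, surface
    area, convex-hull porosity and pore volume of single plants and colony
    cores), and microcosm drought time series (relative water content and
    chlorophyll-fluorescence trajectories by planting density). Includes a
    synthetic-data module that generates voxel phantoms with analytic
    ground truth, simulated centrifugation ledgers built from labelled
    water pools, and simulated drought trajectories, so every analysis
    stage is testable against known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
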