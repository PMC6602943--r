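Package: ahah
Title: Construction of the Access to Healthy Assets and Hazards Index
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds small-area composite indices of neighbourhood access to
    health-promoting assets (health services, green space) and health-negating
    hazards (unhealthy retail, air pollution). Provides a seeded synthetic
    study-region generator (road network with one-way streets, postcode
    centroids, service locations, green-space polygons, pollutant rasters),
    network accessibility scoring via nearest-facility shortest paths,
    buffer-based green-space area and zonal pollutant means, zone-level
    aggregation, rank-based inverse normal (Rankit) standardisation,
    equal-weight domain scores, the exponential rank transformation used by
    the 2015 English Index of Multiple Deprivation, and the overall index
    with deciles. All geometry is planar Cartesian; all outputs are
    deterministic plain-text files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
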