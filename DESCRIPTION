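Package: avoidnull
Title: Spatially Explicit Null Models for Long-Term Social Avoidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies statistically non-random long-term social avoidances
    (and preferences) between pairs of individually identified animals from
    longitudinal sighting records. Builds gridded kernel utilization
    distributions with raster contours and volume-of-intersection overlap,
    forms dyadic half-weight association indices from spatial proximity
    within sampling periods, and compares them against an iterative null
    model that randomizes positions within each individual's utilization
    distribution subject to temporal availability, per-period roster sizes
    and survey-effort geometry. Includes calibration of the null grouping
    distance against observed population sociability, permutation p-values
    with avoid/random/prefer classification, sightings-sufficiency
    diagnostics, and a synthetic-data generator with planted dyadic
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
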