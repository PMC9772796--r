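Package: alsmetrics
Title: Ecosystem Structure Metrics from Airborne Laser Scanning Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for deriving gridded ecosystem-structure
    variables from classified airborne laser scanning (ALS) point clouds.
    Reads and writes LAS and PLY point clouds, retiles them onto a regular
    kilometre grid, normalizes elevations against the lowest point in 1 m
    cells, computes 25 vegetation-structure metrics (height percentiles,
    pulse penetration ratio, vertical band ratios, foliage-height entropy,
    moments and plane-fit roughness) plus point density on a 10 m grid,
    rasterizes them to single-band GeoTIFF, builds and applies a binary
    water/building/road mask from cadastral polygons, and validates the
    vegetation classification against hand-labelled plots. Includes a
    synthetic-scene generator with known ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
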