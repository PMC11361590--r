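Package: tileforge
Title: Threshold-Gated Tile Extraction from Whole Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts square tiles from pyramidal whole-slide images for
    deep-learning dataset construction. Every grid tile is scored against
    hand-drawn annotation polygons with intersection-over-tile (IoT, the
    fraction of the tile covered by the annotated region) and against blank
    slide background with background-over-tile (BoT, the fraction of the
    tile classified as background by a blur/HSV-threshold/dilate pipeline).
    Tiles passing both inclusive thresholds are written to disk together
    with an auditable per-tile manifest. Supports annotation-guided and
    holistic (background-only) extraction, ASAP XML / GeoJSON / plain JSON
    annotations, random tile subsampling, preset threshold ladders, a
    synthetic pyramidal-slide generator with analytic ground truth, and
    extraction-map previews.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    EBImage,
    tiff,
    png,
    jpeg,
    jsonlite,
    xml2,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
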