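Package: coverquant
Title: Color-Threshold Coverage and Area Quantification for Plant Images
Version: 0.1.0
Authors@R:
    person("coverquant", "developers", email = "coverquant@example.org",
           role = c("aut", "cre"))
Description: Per-pixel color-threshold classification of 24-bit raster images
    into foreground, ignored and background classes using RGB or YCbCr color
    similarity under a single global tolerance, with coverage percentages,
    physical areas in cm2 derived from embedded DPI metadata, two-selection
    ratios (e.g. senescent/total tissue), and batch-uniform application of one
    saved color selection to entire image sets. Includes a synthetic fixture
    generator (calibration sheets, two-phase plants, canopy plots) with exact
    ground truth, a 24-bit BMP reader/writer that honours pixels-per-meter
    resolution metadata, and a command-line interface for batch phenotyping
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
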