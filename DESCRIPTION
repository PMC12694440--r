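Package: teaprof
Title: Bulk Tea Shoot Detection and Cutter Profiling from RGB-D Canopy Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for analysing RGB-D images of tea canopies for mechanised
    bulk tea harvesting. Segments young tea shoots from older leaves with an
    excess-green colour index and Otsu thresholding under two lighting regimes
    (CLAHE enhancement in low light, specular-highlight masking with
    zero-excluding Otsu in high light), extracts region-averaged shoot depths
    from the paired depth raster, computes the cutter's height and rotation
    adjustment through the rig's four-bar linkage, and selects a discrete
    motion decision from a configurable band table. Includes a seeded synthetic
    canopy generator with exact ground truth, pixel-level detection metrics and
    field harvest-quality metrics, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
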