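Package: xrfroi
Title: Cell Detection and Fine-Scan Recommendation for X-Ray Fluorescence
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects individual bacterial cells in coarse-resolution
    multi-element X-ray fluorescence (XRF) scan maps, extracts morphological
    and elemental features per cell, embeds cells in a principal-component
    space, clusters them with hard and fuzzy k-means, and recommends ranked
    fine-scan targets with stage coordinates for autonomous microscopy.
    Includes a synthetic-scan simulator with known ground truth (elliptical
    cells, treatment-specific elemental profiles, dwell-time-scaled Poisson
    noise) so the whole pipeline is testable without beamline data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rhdf5,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
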