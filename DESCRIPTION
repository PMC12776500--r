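Package: misalign
Title: Cell-Orientation Disorganization Scoring for Segmented Tissue Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies planar cell-orientation (dis)organization in segmented
    tissue sections using two axial (180-degree periodic) angle statistics: the
    per-cell Global Orientation Angle (GOA), the deviation of a cell's major
    axis from the tissue's proximal-distal axis on a 0-90 degree scale, and the
    Local Misalignment Score (LMS), the folded mean angular difference between
    a cell and its neighbors within a fixed radius, calibrated so that
    perfectly random neighborhoods score 45 degrees. Includes readers for
    QuPath-dialect GeoJSON cell exports and integer label-mask TIFFs,
    sequential marker-region cell classification with hypertrophic-zone
    distance zoning (growth-plate chondrocyte workflows), a
    Wasserstein-distance ratio permutation test over embryo-level samples, a
    synthetic segmented-tissue generator for validation, and fixed-scale
    heatmap rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
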