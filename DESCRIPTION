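Package: woundquant
Title: Automated Quantification of Wound-Healing Scratch Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures cell-migration rates from phase-contrast micrographs of
    wound-healing (scratch) assays. The monolayer is split into cell and
    wounded areas by local-texture segmentation, the cell/wound boundary
    contours are traced at subpixel precision, and the wound-gap width is
    measured along N equally-spaced lines perpendicular to the wound main
    axis. Includes the standard assay arithmetic (relative migration distance
    as a percentage of control closure, caliper tumour volume, normalisation
    to control), a synthetic scratch-image generator with exact ground truth
    for validation, and a configuration-driven batch runner with CSV/JSON
    output and QC overlays.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    withr,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
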