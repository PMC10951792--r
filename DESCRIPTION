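Package: celltyper
Title: Headless Cell Detection, Feature Extraction and Rule-Based
    Cell-Type Classification for 2D Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for classifying cells in 2D multi-channel
    fluorescence microscopy images. Cells are detected on a primary marker
    channel by global auto-thresholding (sixteen classical histogram methods)
    with optional watershed splitting of touching objects, per-cell shape and
    intensity features are extracted across up to three marker channels,
    bright foci are counted per nucleus by intensity prominence, and cells are
    assigned to user-defined cell types through declarative interval and
    cross-feature constraints. A complete analysis is serialized as an
    editable XML configuration and can be replayed over directories of images
    in batch mode with CSV outputs. A synthetic-scene generator with exhaustive
    ground truth supports validation without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    igraph,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
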