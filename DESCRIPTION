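Package: slidekit
Title: Headless Annotation Management for Whole-Slide and Large Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for managing expert annotations on
    whole-slide and large microscopy images without a server: an annotation
    data model with templates and products, pseudonymised image naming,
    git-like version snapshots of image sets with artifact attachment and
    virtual train/validation/test splits, persistent guided-screening patch
    grids with 15 percent overlap, validation images (per-label annotation
    maps, embedding cluster maps, and score-ordered density maps) with exact
    coordinate back-mapping from the generated image to the source
    annotations, crowd-annotation visibility and completion policies, and a
    deterministic synthetic-slide generator for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    withr,
    png,
    tiff,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
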