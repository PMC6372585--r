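Package: glomorph
Title: Glomerular Morphometry by Serial-Section 3D Reconstruction,
    Cavalieri Point Counting, and Planimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for quantifying glomerular mesangial morphology from
    serial histology sections. Implements three comparator methods: watertight
    3D reconstruction of aligned contour stacks by prism extrusion, Cavalieri
    point-count volume estimation with systematic uniform random grids
    (including the point-sampled-intercept fractional volume Vv(mes/glom)),
    and planimetry of traced profiles. Includes landmark-based rigid
    registration of serial sections, colour-deconvolution segmentation of
    PAS-stained images, a synthetic glomerulus phantom generator with exact
    voxel ground truth, and a repeated-measures method-comparison harness
    (within-subject ANOVA, post-hoc contrasts, correlations).
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
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
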