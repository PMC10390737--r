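Package: slicequant
Title: Quantitative Image and Expression Analysis of Focal Injury in Organotypic Brain Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify a focal contusion in organotypic cortical slice
    cultures from fluorescence microscopy and qPCR data. Implements radial
    cell-death profiling over concentric regions of interest centred on the
    lesion (normalized integrated density and area under the radial profile),
    a segmentation/skeletonization pipeline for neurite morphometry (background
    floor, disk median filter, Li minimum cross-entropy thresholding, extended
    focus, topology-preserving thinning and skeleton-graph branch metrics),
    percent stained area and single-cell shape descriptors for glial channels
    (area, perimeter, Feret diameter, circularity behind a size gate),
    delta-delta-Ct relative gene expression, and the group statistics used for
    such studies (Shapiro-Wilk gated parametric/rank tests, one- and two-way
    ANOVA with Tukey or Sidak post-hoc procedures). A synthetic lesioned-slice
    generator with per-object ground truth makes every stage testable without
    raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    car,
    emmeans,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
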