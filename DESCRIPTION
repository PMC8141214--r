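Package: segvol
Title: Refinement of 3D Nuclear Instance Segmentations from Light-Sheet Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for creating and refining 3D nuclear instance
    segmentations of light-sheet microscopy volumes. Provides global
    threshold-based pre-segmentation with connected-component labeling,
    voxel- and region-level editing (brush paint and erase, intensity- and
    distance-constrained in-plane region growing and shrinking, merging, and
    semi-automated splitting of incorrectly joined nuclei by threshold sweep
    and seeded growth), region bookkeeping with a JSON status sidecar,
    Dice-based inter-rater reliability checks, paired timing statistics, a
    synthetic nuclear-image generator with ground-truth labels, and a
    command-line interface. Volumes are read and written in TIFF (single
    multi-page file or per-slice stacks) and NIfTI-1 formats.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
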