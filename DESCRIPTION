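Package: cortexscale
Title: Multiscale Coarse-Graining Morphometrics for Cortical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grains the cortical ribbon bounded by pial and white
    matter surfaces into occupancy grids at a sequence of spatial scales,
    erasing folds smaller than each scale while preserving surface integrity,
    and measures the resulting realisations (total area, exposed convex-hull
    area, average thickness). Provides isometric rescaling, orthogonal K/I/S
    shape coordinates, universal scaling-law and fractal-dimension fitting
    (area-scaling and box-counting routes), synthetic surfaces with
    controllable scale structure (slabs, sphere shells, folded shells,
    fractional-Brownian fractal shells, two-group cohorts) and scale-resolved
    group comparison with Cohen's d and rank-sum z effect curves. Reads and
    writes FreeSurfer binary, OFF, PLY and STL surfaces and NIfTI or JSON
    occupancy grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse
Config/testthat/edition: 3
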