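Package: spatialconcord
Title: Quality Control and Cross-Modality Concordance Analysis for
    Imaging-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the downstream analysis of multiplexed-FISH
    (MERFISH-style) spatial transcriptomics and its comparison with
    single-cell RNA sequencing. Provides transcript-to-cell assignment by
    projecting median z-slice segmentation boundaries through the imaging
    volume, image-anchored cell quality control using an average-DAPI
    alignment score, bulk and single-cell concordance statistics (replicate
    and pseudo-bulk correlations, dropout rates, detection fractions,
    nonzero-cell means, mean-variance analysis and negative-binomial
    fitting), a spatial cell-type co-occurrence probability ratio, a
    cross-modality cosine-similarity diagnostic with annotation confusion
    matrices, and a synthetic tissue generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
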