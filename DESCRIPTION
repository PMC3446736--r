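Package: vbmperm
Title: ROI and Voxel-Based Morphometry Association Models with
    Max-Cluster-Size Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for relating a subject-level exposure score (for
    example a factor-based social-engagement score) to structural-MRI
    brain volumes.  Implements per-region standardized-coefficient OLS
    models with covariate adjustment and effect-modification tests,
    temporal-reversal models on five-year volume change, and a voxel-wise
    general linear model on tissue-density map stacks with
    suprathreshold-cluster extraction and a max-cluster-size permutation
    test for family-wise error control.  Includes a synthetic-cohort
    generator (covariates, ordinal scale items driven by one latent
    factor, region volumes, and 3-D tissue maps with embedded effect
    blobs) so the full pipeline can be exercised and calibrated without
    access to cohort MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
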