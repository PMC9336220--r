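Package: cascnr
Title: Causal Structural Covariance Network Analysis of Gray-Matter Volume Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based-morphometry style analysis of co-registered gray-matter
    volume (GMV) maps, centred on causal structural covariance networks (CaSCN):
    patients are ordered by illness duration into a pseudo time series, the mean
    GMV of a seed region is extracted, and a signed-path-coefficient Granger
    causality regression maps where GMV change follows (or opposes) change in the
    seed. Includes optimal-threshold (Otsu) masking, covariate-adjusted voxelwise
    general linear models with t contrasts, duration-based stage splitting,
    Gaussian-random-field cluster-level correction with residual-based smoothness
    estimation, a permutation oracle for cluster inference, and a synthetic
    phantom generator that plants duration-driven seed atrophy with a one-step
    lagged follower region so the whole pipeline is testable without real MRI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    readr,
    rlang,
    generics,
    igraph,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    purrr,
    oro.nifti,
    MASS,
    withr
Config/testthat/edition: 3
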