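Package: sbmtools
Title: Source-Based Morphometry with Spatial ICA and Brain-Behavior
    Canonical Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes stacked voxel-based morphometry gray-matter density
    maps into spatially independent covariation components with per-subject
    loadings (source-based morphometry), tests component loadings for group
    differences with covariate-adjusted linear models and false discovery
    rate control, performs mass-univariate voxelwise inference with
    Freedman-Lane permutation and threshold-free cluster enhancement (TFCE),
    and relates component loadings to symptom batteries through
    permutation-tested canonical correlation analysis with leave-one-out and
    subsampling stability diagnostics. Includes a synthetic phantom generator
    with known spatial sources, planted group effects and a planted canonical
    mode, so the whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
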