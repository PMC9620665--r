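Package: nftburden
Title: Neurofibrillary Tangle Burden Metrics and Spatial Clustering Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies neurofibrillary tangle (NFT) burden from segmentation
    outputs of digitized, p-tau immunostained hippocampal sections and relates
    it to antemortem cognitive status. Reads per-slide NFT object tables,
    region annotations (hippocampus proper, entorhinal cortex) and cohort
    covariate tables; extracts NFT instances from per-pixel probability maps;
    computes regional burden measures (count density, NFT positive-pixel
    density, normalized positive-pixel burden); computes the mean clustering
    coefficient of the radius-threshold geometric graph over NFT centroids
    across a sweep of distance thresholds; and runs the clinicopathologic
    statistical battery (Yates and Pearson chi-square tests,
    Cochran-Mantel-Haenszel stratified odds ratios, Welch t-tests, rank and
    product-moment correlations, per-SD logistic odds ratios with and without
    age adjustment, Benjamini-Hochberg false discovery rate control, and
    odds-ratio-versus-radius curves). A synthetic cohort generator built on
    homogeneous Poisson and Thomas cluster point processes reproduces the
    statistical structure the analysis assumes, so the full pipeline is
    testable without access to autopsy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
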