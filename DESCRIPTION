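Package: hofcnet
Title: Low- and High-Order Functional Connectivity Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and graph-theoretic analysis of low-order (Pearson)
    and high-order (correlation-of-correlation-profiles) functional
    connectivity networks from region-of-interest rs-fMRI time series.
    Provides a synthetic two-group cohort generator with planted modular
    effects, ROI-level temporal preprocessing (detrending, zero-phase
    band-pass filtering, nuisance regression), sparsity thresholding,
    global and nodal graph metrics normalized by degree-preserving rewired
    null networks, modular and rich-club organization, the network-based
    statistic with permutation family-wise-error control, and a nested
    leave-one-out LASSO + linear SVM classifier.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
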