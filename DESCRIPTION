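Package: ehecco
Title: Joint Hilbert Embedding Metrics for Motion Capture Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based distances between probability distributions for
    multichannel kinematic time series. Implements the maximum mean
    discrepancy (MMD) between marginal distributions and the EHECCO metric
    (enhanced Hilbert embedding from cross-covariance operators) between
    joint distributions embedded in a tensor reproducing kernel Hilbert
    space, together with a complete skeletal action-recognition pipeline
    for motion-capture data: BVH reading/writing and forward kinematics,
    hip-based normalization, spectral-clustering pose codebooks, a
    PCA-based latent view, dissimilarity-space SVM classification with
    cross-validated grid search, t-SNE visualization, anthropometric
    covariate correlation, and a synthetic articulated-skeleton motion
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
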