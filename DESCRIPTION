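Package: signsynergy
Title: Principal Movement Analysis of Upper-Body Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes continuous upper-body motion capture recordings into
    principal movements (PMs): postural synergies extracted by principal
    component analysis of pelvis-referenced, per-subject normalized posture
    vectors. Implements the two-step anthropometric normalization (mean-posture
    centering and mean-Euclidean-norm scaling), PCA decomposition with weight
    time series, zero-phase Butterworth low-pass filtering of the weights,
    Welch power spectral density estimation, PM resynthesis into 3D marker
    trajectories, and three comparison procedures: leave-one-out orientation
    robustness of the components, cosine similarity between PMs, and symmetric
    cross-projection subspace similarity. Includes a synthetic multi-signer
    cohort generator with planted synergy structure for validation, readers
    and writers for TRC and CSV marker trajectories, and reporting utilities
    (explained-variance tables, point-light-display exports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
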