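Package: anomrecon
Title: Reconstruction-Based Anomaly Detection and Localization in Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model-agnostic toolkit for reconstruction-based anomaly detection
    in 2-D medical images. Test images are reconstructed by gradient-based
    latent optimization against a generative backend and scored with mean
    squared error and a spatially invariant 1-D Wasserstein distance; local
    anomalies are localized via the highest-error patch. Includes a
    differentiable parametric phantom backend, Frechet-distance fidelity
    metrics with a pluggable feature extractor, subsampled AUROC evaluation,
    one-sided permutation tests with simulation-based power analysis, DICOM/PNG
    preprocessing (CT windowing, linear rescaling, body masking), and a seeded
    synthetic fixture generator with ground-truth anomaly masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
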