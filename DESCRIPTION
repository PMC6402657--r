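Package: riemix
Title: Adaptive Riemannian Mixture-of-RVM Classification for Multi-Class EEG
    Brain-Computer Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Online co-adaptive four-class brain-computer interface pipeline
    built on the Riemannian geometry of spatial covariance matrices.
    Covariance descriptors of band-passed EEG segments are treated as points
    on the manifold of symmetric positive-definite matrices; per-trial Karcher
    means drive a representative-sample selection rule, multi-class common
    spatial patterns (approximate joint diagonalization with mutual-information
    component ranking) reduce dimensionality, and sparse multinomial-probit
    relevance vector machines trained on tangent-space features are combined
    into an adaptively weighted mixture whose weights track both supervised
    confusion-matrix quality and the Riemannian distance of incoming data to
    each sub-model's reference mean. Includes the matching evaluation suite
    (confusion-matrix quality, pairwise class separability, instability via
    tangent-space PCA, exact left-tail Wilcoxon signed-rank tests, per-subject
    regression over runs), EDF/BrainVision ingestion with Butterworth
    band-pass, notch and polyphase resampling, a replay simulator of the
    run/trial feedback protocol, and a seeded generator of synthetic
    multi-channel sessions whose class structure lives in the spatial
    covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
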