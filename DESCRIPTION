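Package: fatiguefuse
Title: Exercise Fatigue Estimation from Fused ECG and sEMG Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating exercise-induced fatigue states from
    synchronously recorded electrocardiogram (ECG) and two-channel surface
    electromyography (sEMG) signals. Provides a seeded synthetic-signal
    generator emulating three fatigue states (relaxed, transition, tired), a
    preprocessing chain (zero-phase low-pass filtering, adaptive 50 Hz notch
    cancellation, denoising of initial empirical-mode-decomposition components
    by wavelet thresholding), extraction of eleven fatigue-related features
    (heart-rate-variability indices from the RR tachogram and time/frequency
    sEMG indices), a particle-swarm-optimized feature-fusion one-vs-one
    support vector machine classifier with a radial basis kernel, and Monte
    Carlo cross-validation with baseline classifiers (back-propagation neural
    network, k-nearest neighbours, linear discriminant analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    nnet,
    MASS,
    class,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
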