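Package: g4family
Title: Balanced Confusion-Matrix Metrics for Binary Classifier Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating binary classifiers with the balanced
    metric family - G4 (the geometric mean of sensitivity, specificity,
    PPV and NPV), P4 (their harmonic mean) and the scaled Matthews
    correlation coefficient - alongside the standard confusion-matrix
    metric zoo and trapezoidal AUROC. Includes a binormal simulation
    engine that converts a nominal AUROC to Cohen's D and tabulates
    prevalence-specific benchmarks for the family, a stratified clustered
    case-resampling bootstrap for multi-reader multi-case (MRMC)
    standalone and between-modality inference, integer confusion-matrix
    reconstruction from published summary rates, and simulation-based
    power and sample-size estimation for G4 benchmark tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
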