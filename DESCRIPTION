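Package: ddtpso
Title: Dynamic Hybrid Dipper-Throated and Particle Swarm Optimization for
    Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Population-based continuous optimization combining dipper-throated
    optimization (DTO) and particle swarm optimization (PSO) under a dynamic
    strategy-swapping controller (DDTPSO), together with its binary
    feature-selection variant (bDDTPSO): sigmoid transfer-function
    binarization, K-nearest-neighbour wrapper fitness, and a full evaluation
    harness with classification metrics, run statistics, one-way ANOVA,
    Wilcoxon signed-rank tests and linear regression reports. Includes
    class-quota image augmentation (flips and 90-degree rotation), synthetic
    feature-table and image generators for validation, classifier
    hyperparameter tuning driven by the optimizer, and a staged pipeline with
    CSV/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    class
Config/testthat/edition: 3
RoxygenNote: 7.3.3
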