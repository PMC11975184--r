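Package: choopt
Title: Machine-Learning-Guided Optimization of CHO Fed-Batch Cultivation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and machine-learning optimization loop for fed-batch
    Chinese Hamster Ovary (CHO) antibody production processes: a calibrated
    kinetic simulator of daily-sampled cultivation runs, schema-validated
    JSON run storage, cleaning and iterative impurity-based feature
    selection, multi-output surrogate regressors (linear, partial least
    squares, random forest and a feedforward neural network) with
    cross-validated comparison, mass in-silico screening of candidate
    process settings with titer filtering and diversity-aware proposal
    selection, and in-silico validation of the proposals against the
    ground-truth simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    mixOmics,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
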