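Package: camtrapeval
Title: Evaluation of Pre-Trained Image Classifiers for Camera-Trap Species Detection
Version: 1.0.0
Authors@R: person("Karlovac", "Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for turning multi-class top-5 image-classifier output into
    binary species detections and evaluating the detectors on highly
    imbalanced camera-trap datasets. Maps WordNet synset predictions to a
    target species (Eurasian lynx by default), computes the full
    confusion-matrix metric suite (sensitivity, specificity, precision,
    accuracy, balanced accuracy, geometric mean, Youden's index, discriminant
    power, F1, Matthews correlation coefficient, Cohen's kappa), selects
    top models by kappa, and builds and tunes threshold-voting ensembles.
    Includes a Gaussian-copula synthetic-data generator emulating rare
    positives and correlated per-model detections, CSV/JSONL/SQLite
    persistence, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
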