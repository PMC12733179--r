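Package: fola
Title: Direct F-Beta Score Optimization via Cost-Sensitive Weighted Cross-Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trains binary and multi-label classifiers to maximize the F-beta
    score by reduction to cost-sensitive learning. The positive-class weight of
    a weighted binary cross-entropy loss is derived in closed form from
    precision and recall, and re-estimated once per epoch from validation
    metrics (the Fola algorithm), with per-label weights and median-based
    weight bounding for macro-averaged objectives. Includes a differentiable
    soft F-beta loss baseline, a reference per-label logistic learner,
    generators for imbalanced synthetic multi-label tasks with known posterior
    probabilities, and brute-force and fixed-point oracles that verify the
    optimality of the derived weights at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
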