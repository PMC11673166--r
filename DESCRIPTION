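Package: statgan
Title: Statistics-Conditioned GAN for Synthetic Medical Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic patient-level tabular data from summary
    statistics alone. A table schema describes per-column ranges, clinical
    risk thresholds and a binary outcome; a statistics vector (per-column
    min, max, mean, risky-value fraction and odds ratio against the outcome)
    conditions a generative adversarial network trained with a custom
    table-similarity loss that compares tables row-wise rather than
    cell-wise. Includes the statistics-constrained corpus builder used for
    training, a univariate resemblance assessment (t-test, chi-square,
    Wasserstein distance with Excellent/Good/Poor labelling) for fidelity,
    and train-on-synthetic/test-on-real (TSTR vs TRTR) utility evaluation
    with four reference classifiers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    ranger,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
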