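Package: bagclock
Title: Balanced Bagging Ensemble Clocks for DNA Methylation Age Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds DNA-methylation "clock" models that predict chronological
    age accurately across the whole age range even when the training data have
    a biased age distribution. The core method combines bagging with a
    regression variant of SMOTE to rebalance the training age distribution,
    selects features with cross-validated elastic-net base learners, and
    combines ordinary linear re-fits into a weighted ensemble. The package
    also provides a plain bootstrapped bagging clock and a single
    penalized-regression clock for comparison, a kernel-density balance index
    to diagnose age-distribution bias, conversion of Illumina probe-level beta
    values to gene- and DMR-level features with annotation, evaluation plots
    (density-colored scatter, residual curves, polar clock dials), and a
    seeded synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    MASS,
    jsonlite,
    data.table,
    withr,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
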