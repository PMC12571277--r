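Package: crisprtransfer
Title: Similarity-Guided Source Selection for CRISPR-Cas9 Off-Target
    Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing a source dataset before running transfer
    learning on small, heavily imbalanced CRISPR-Cas9 off-target datasets.
    Aligned sgRNA-DNA pairs are encoded with a seven-bit-per-position binary
    scheme (five character bits over A, C, G, T and the gap symbol, plus a
    two-bit mismatch/indel direction channel), dataset-to-dataset distances
    are estimated by Monte-Carlo minimum-distance search under cosine,
    Euclidean or Manhattan metrics, distance matrices are min-max normalized
    into similarities, and the most similar source is recommended for each
    bootstrapped target. A transfer-learning harness trains shallow
    classifiers (logistic regression, random forest, one- and two-hidden-layer
    perceptrons) on a source and scores them on a target with AUC-ROC,
    precision, recall, F1, Brier score and accuracy. A synthetic-data module
    generates benchmark-like guide sets with controlled mismatch and indel
    spectra and extreme class imbalance so the whole workflow is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
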