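Package: saesvdd
Title: One-Class Classification of Imbalanced Questionnaire Data with
    Stacked-Autoencoder Support Vector Data Description
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects rare "abnormal" respondents (e.g. antenatal depression
    cases) in imbalanced, high-dimensional binary questionnaire data using a
    one-class pipeline: a stacked autoencoder embeds the sparse 0/1 answer
    matrix into a low-dimensional code space, affinity propagation partitions
    the healthy (target) class into sub-clusters, and a kernel support vector
    data description hypersphere is fitted per sub-cluster with penalty and
    kernel width tuned by particle swarm optimization against a
    cross-validated F-score. A sample is classified as target if it falls
    inside any sub-hypersphere. Also provides an improved TF-IDF statistic and
    information gain for ranking questionnaire options by their association
    with the abnormal class, a seeded synthetic-data generator with known
    cluster structure and risk options, LIBSVM/CSV readers, model
    serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    cluster,
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
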