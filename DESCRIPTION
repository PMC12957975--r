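Package: gsrnet
Title: Sparse and Group-Sparse Functional Connectivity Networks with
    Nested Cross-Validated Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds functional brain-connectivity networks from
    region-of-interest (ROI) time series by three routes - pairwise
    Pearson correlation, per-subject sparse representation (l1-penalized
    node-wise regression), and group sparse representation
    (l2,1-penalized multi-subject regression enforcing a shared edge
    support) - and evaluates their diagnostic value with LASSO feature
    selection and a linear support-vector machine under nested
    leave-one-out cross-validation with majority voting.  Includes a
    synthetic-cohort generator with known precision-matrix ground truth,
    discriminative-connection aggregation onto the AAL-116 atlas, and
    demographics comparison utilities (normality-gated two-sample tests,
    chi-square on 2x2 tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
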