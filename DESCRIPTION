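Package: ennet
Title: Gene Regulatory Network Inference by Gradient Boosting of
    Regression Stumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from steady-state,
    knockout and multifactorial expression compendia. Each gene's
    expression is modelled by gradient boosting of regression stumps over
    candidate transcription factors; the accumulated least-squares
    improvement of each factor yields a weighted adjacency matrix, which
    is refined by a row-variance transform and, when knockout profiles
    are available, a knockout z-score transform. Includes DREAM-dialect
    readers and writers, AUPR/AUROC evaluation against gold-standard
    edge lists, cross-validated tuning of the sampling rates, a stability
    check across independent runs, and a linear steady-state simulator
    that generates gold-standard networks with matching expression and
    perturbation matrices for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
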