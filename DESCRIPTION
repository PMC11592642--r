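Package: icomproc
Title: Information-Complexity Model Selection for ROC Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for scoring Receiver Operating Characteristic (ROC) curve
    models with information criteria. Builds Bi-distributional (Universal) ROC
    curves over seven probability families (Normal, Exponential, Weibull, Gamma,
    minimum extreme value, generalized extreme value, generalized Pareto) fitted
    by maximum likelihood, computes AUC by adaptive Gauss-Kronrod quadrature,
    and scores candidate models with AIC-ROC and the information-complexity
    criterion ICOMP-ROC derived from the inverse Fisher information matrix of
    the standardized bivariate normal via duplication-matrix algebra. Includes a
    Monte Carlo harness for distribution-pair recovery experiments, confusion
    matrix metrics and cross-validated evaluation of standard binary classifiers,
    genetic-algorithm feature-subset selection, and synthetic data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    generics,
    ggplot2,
    withr,
    pracma,
    jsonlite,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
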