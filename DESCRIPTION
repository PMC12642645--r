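Package: fccomm
Title: Assumption-Lean Community Detection for Weighted Functional-Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community detection on dense weighted functional-connectivity
    matrices without thresholding or assortativity assumptions. Implements a
    Gaussian weighted stochastic block model fitted by mean-field variational
    Bayes, spectral clustering on the unnormalized graph Laplacian, and
    K-means under a correlation dissimilarity; selects the number of
    communities via bootstrap confidence intervals on differences of
    successive-K log-likelihoods; provides partition-quality indices
    (silhouette, modularity, variation of information, normalized mutual
    information, Calinski-Harabasz, C-index, Dunn) and a Hungarian-matching
    consensus algorithm, plus a synthetic planted-block connectome generator
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
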