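Package: dynega
Title: Dynamic Exploratory Graph Analysis for Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of latent topics or factors driving a
    multivariate time series by combining time-delay embedding, generalized
    local linear approximation (GLLA) derivative estimation, regularized
    network estimation (EBIC-tuned graphical LASSO or the triangulated
    maximally filtered graph), and Walktrap community detection. Includes the
    total entropy fit index (TEFI) for tuning the number of embedding
    dimensions, network loadings and network topic scores, a direct
    autoregressive factor score (DAFS) simulator, a Monte Carlo evaluation
    harness, and text utilities to build document-term matrices from raw
    corpora (tokenization, stopword removal, Porter stemming, sparsity
    filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
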