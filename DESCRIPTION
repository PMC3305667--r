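Package: bgmlasso
Title: Binary Graphical Models via Penalized Logistic Regression and the
    Bolasso
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure learning for undirected graphical models over
    high-dimensional binary data. Estimates each node's neighborhood by
    L1-penalized logistic regression (penalty chosen by cross-validation,
    AIC, BIC, or a target neighborhood size), optionally stabilized by
    bootstrap aggregation (Bolasso), and combines neighborhoods into an
    edge set by the AND- or OR-rule. Includes a Gibbs sampler for binary
    Markov random fields parameterized by a symmetric odds-ratio matrix,
    an exact-enumeration oracle for small graphs, graph evaluation by
    Structural Hamming Distance and Youden index, and a simulation-study
    driver that sweeps sample size, bootstrap count, selection threshold
    and neighborhood size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
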