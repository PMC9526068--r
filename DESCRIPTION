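Package: coalratios
Title: Exact Moments and Ratio Approximations for Coalescent Tree Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact finite-sample expectations, variances, and covariances of six
    summaries of Kingman-coalescent genealogies -- tree height, total branch
    length, total external and internal branch lengths, mean basal branch
    length, and the inter-coalescence times -- together with delta-method
    (Taylor) approximations to the expectation and variance of all fifteen
    pairwise ratios of these summaries, their exact large-sample limits over
    the constant basis {1, pi^2, pi^4, pi^6, zeta(3), pi^2 zeta(3)}, and a
    seeded coalescent simulator for Monte-Carlo validation. Finite-sample
    values are computed in arbitrary-precision rational arithmetic so that
    algebraic identities can be tested exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    BH
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
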