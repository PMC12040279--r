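Package: snqtl
Title: Spectral Network QTL Mapping of Gene Co-Expression Networks
Version: 1.0.0
Authors@R: person("snqtl", "developers", email = "snqtl@example.org",
    role = c("aut", "cre"))
Description: Tests, at each genetic marker of a hybrid cross, whether the
    genotype classes (AA/AB/BB) differ in their gene co-expression networks.
    Pairwise differences of genotype-group Pearson correlation matrices are
    stacked into a p x p x 3 differential tensor and summarized by sparse
    spectral statistics: the sparse leading tensor eigenvalue obtained by
    sparse symmetric tensor decomposition, and the maximal sparse leading
    matrix eigenvalue obtained by penalized matrix decomposition. Empirical
    p-values come from a two-stage permutation scan. At significant markers
    the joint differential network (gene leverages, edge weights, and
    genotype-comparison loadings) is estimated. Includes an F2-intercross
    simulator with Poisson read counts and a planted network QTL so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
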