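Package: msatcoal
Title: Microsatellite Population Genetics and Coalescent ABC for
    Colonization History
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diploid microsatellite datasets: GenePop and CSV
    input/output, per-population diversity tables and Nei F-statistics,
    Hardy-Weinberg and linkage-disequilibrium testing, null-allele
    estimators, individual heterozygosity indices (PHt, Hs_exp, IR, HL),
    chord and shared-allele distances with neighbor-joining trees and
    Mantel isolation-by-distance tests, a discrete-generation coalescent
    simulator for microsatellites under a generalized stepwise mutation
    model with declarative demographic scenarios, approximate Bayesian
    computation (rejection plus local logistic regression) for scenario
    choice and parameter estimation, joint Bayesian estimation of
    inbreeding and null-allele frequencies via Gibbs sampling, and a
    synthetic-data generator emulating a coastal isolation-by-distance
    microsatellite survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
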