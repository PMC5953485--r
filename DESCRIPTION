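Package: pedcontrib
Title: Marginal Ancestral Genetic Contributions in Case-Control Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree analysis of a binary trait in a managed population via
    probabilities of gene origin: raw and marginal genetic contributions of
    ancestors to overlapping birth-year cohorts of affected and control
    animals (iterative decomposition with pseudo-founder pruning), classical
    pedigree statistics (inbreeding, additive relationship, pedigree
    completeness index), paired t-test comparison of ancestral contributions
    with Benjamini-Hochberg false-discovery-rate control, five-generation
    appearance profiles, and a liability-threshold disease simulator with
    popular-sire pedigree structure for validating the pipeline end to end.
    Ships the published contribution and t-test tables of a Standardbred
    atrial-fibrillation case-control study as machine-readable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
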