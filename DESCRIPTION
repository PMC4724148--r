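Package: codonsel
Title: Selection Regimes from Codon Models with Phylogenetic Comparative
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood inference of selective constraint on
    protein-coding genes using Goldman-Yang style codon substitution
    models: one-ratio (M0), two-ratio branch models, free-ratio, and
    branch-site model A with its fixed null, fitted by Felsenstein
    pruning with a compiled likelihood kernel.  Provides likelihood
    ratio tests and a decision table that classifies foreground clades
    as conserved, positively selected or relaxed; per-branch dN and dS
    decomposition and root-to-tip omega statistics; Bayes empirical
    Bayes detection of positively selected sites; domain splitting,
    arginine-content and Welch comparisons for sperm nuclear proteins;
    and phylogenetic generalized least squares with maximum-likelihood
    estimation of Pagel's lambda.  Includes a simulator for codon
    alignments evolved under branch and branch-site regimes and for
    continuous traits with lambda-structured phylogenetic noise, plus a
    pipeline that reproduces the full selection and comparative
    analysis from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    MASS,
    Rcpp,
    seqinr,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
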