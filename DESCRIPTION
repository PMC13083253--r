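Package: urvscan
Title: Rare-Variant Discovery Pipeline for Unbalanced Case-Control Exome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rare-variant association analysis in large, unbalanced,
    multi-cohort case-control exome studies. Implements Firth bias-reduced
    logistic regression with profile penalized-likelihood confidence intervals
    and penalized likelihood-ratio tests, ultrarare-variant burden testing over
    genes, protein domains and genesets with Cauchy (ACAT) omnibus combination,
    sample- and variant-level quality control including a control-control
    batch-effect scan and greedy unrelated-set selection, oligogenic
    dose-response and permutation co-occurrence testing, sample-size-weighted
    Stouffer meta-analysis with winner's-curse effect-size correction,
    simulation-based power analysis, and age-at-onset and survival models for
    variant carriers. A synthetic-cohort generator with known ground truth
    makes every stage testable without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
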