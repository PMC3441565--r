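Package: pathmtl
Title: Sample-Specific Pathway Enrichment and Multi-Task Learning for
    Integrating Expression and Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts matched gene-expression and genotype data into
    sample-specific pathway enrichment scores using class-conditional
    correlation statistics and a weighted Kolmogorov-Smirnov running sum,
    collapses SNP-level genotypes to genes via chi-square association with
    phenotype, and builds predictive models over the enrichment-score
    feature space with a regularized multi-task support vector machine and
    five comparison models (single-task, concatenated, summed prediction,
    summed enrichment score, merged).  Includes a genotype-expression
    simulator with an additive liability disease model and an experiment
    harness for predictive-accuracy and gene-set rank-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
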