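Package: crosspheno
Title: Cross-Phenotype GWAS Comparison of Two Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical framework for comparing and contrasting genome-wide
    association results between two related diseases across multiple
    case-control cohorts. Implements a compare-and-contrast meta-analysis
    (CCMA) max-z statistic with analytic and Monte-Carlo null calibration,
    a Bayesian partition-model meta-analysis with a composite
    disease/ethnicity distance prior and Bayesian false discovery
    probability filtering, multinomial case-case-control regression with
    Wald linear contrasts and minimum-p effect classification, stepwise
    conditional dissection of multi-signal regions, LD-based clumping and
    locus definitions, standard GWAS quality control, a synthetic
    multi-cohort data generator with known variant classes, and a genotype
    enumeration model quantifying how much opposing risk alleles explain
    epidemiological mutual exclusivity of the two diseases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
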