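Package: bayesmv
Title: Multi-Trait Bayesian Mixture Models for QTL Mapping and Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression with spike-and-mixture-of-normals priors on
    SNP effects, in a univariate form (BayesR) and a multivariate form (BayesMV)
    that shares a per-SNP association indicator across traits while estimating
    effects independently per trait. Includes the error-decorrelating linear
    combination transform for multi-trait analysis, PLINK bed/bim/fam input and
    output, a pedigree numerator relationship matrix, an LD-structured genotype
    and phenotype simulator with pleiotropy scenarios, and evaluation tools for
    prediction accuracy, bias, QTL-mapping power and false discovery rate, and a
    multi-trait single-SNP association scan.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
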