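Package: spdc
Title: Sparse Partial Diallel Crossing Designs and Genomic Prediction of
    Single-Cross Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genomic hybrid breeding built around sparse partial
    diallel crossing between heterotic groups. Generates and audits crossing
    plans, infers hybrid genotypes from inbred parents with additive and
    dominance codings, fits the additive+dominance genomic mixed model by
    EM-REML, predicts all potential single crosses with GBLUP, BayesB or
    LASSO, derives genomic estimates of general combining ability (GCA),
    builds and evaluates GWAS-consensus marker sets, classifies trait-
    associated SNPs by their inbred/hybrid genotype-class behaviour, and
    computes top-selection gains for field validation. Includes a seeded
    synthetic-population simulator (structured inbred panels, diallel hybrid
    sets, QTL-controlled traits at a target heritability) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
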