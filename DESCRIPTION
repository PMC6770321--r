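Package: wheatgp
Title: Genomic Prediction and Association Mapping for Inbred Breeding Cohorts
Version: 0.1.0
Authors@R:
    person("Nordic", "Breeder", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection studies in advanced inbred breeding
    material: a single-seed-descent breeding-cohort simulator with ground-truth
    records, marker quality control and VanRaden genomic relationship matrices
    (full, leave-one-chromosome-out, and significance-partitioned), AI-REML
    variance components and GBLUP (single- and two-kernel genomic feature
    models), single-marker mixed-model GWAS with genomic control, a Bayesian
    Power Lasso whole-genome regression sampler with DIC-based shape selection,
    and a cross-validation engine covering leave-one-out, leave-family-out,
    leave-set-out, k-fold, and training-fraction designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    yaml,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Config/testthat/edition: 3
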