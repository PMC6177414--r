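Package: psasig
Title: Genetic Subtype Classification and Risk Assessment for Psoriatic
    Arthritis
Version: 0.1.0
Authors@R:
    person("psasig", "maintainers", email = "maintainers@psasig.example.org",
           role = c("aut", "cre"))
Description: End-to-end statistical-genetics pipeline for distinguishing
    psoriatic arthritis (PsA) from cutaneous-only psoriasis (PsC) using
    genotype dosages from multiple case-control cohorts. Provides marker
    quality control and per-cohort logistic Wald association tests,
    fixed-effects inverse-variance meta-analysis with genomic control, an
    indirect case-case chi-square statistic for comparing two case-control
    scans, stepwise conditional feature selection coupled to cross-validated
    classification, a registry of classifiers with AUROC and top-k risk
    stratification metrics, prevalence-calibrated individual risk assessment
    via Bayes' theorem with kernel density estimates, a tenfold ensemble with
    per-fold selection and rank combination, leave-one-cohort-out
    evaluation, and enrichment of associated markers in regulatory-element
    intervals. A bundled multi-cohort genotype simulator emulates the data
    structure the analysis assumes, so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite,
    yaml,
    Rcpp,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
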