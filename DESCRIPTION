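Package: epistasurv
Title: SNP-Interaction Discovery and Survival Validation for Pharmacogenetic Cohorts
Version: 0.1.0
Authors@R:
    person("Epistasurv", "Developers", email = "epistasurv@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacogenetic interaction analysis of treatment
    response in clinical cohorts. Implements a from-scratch multifactor
    dimensionality reduction (MDR) search over SNP combinations with
    cross-validated balanced accuracy and permutation-based empirical
    p-values, responder dichotomization by a progression-free-survival
    window, Kaplan-Meier / log-rank / Cox proportional-hazards validation
    of the resulting favorable and unfavorable genotype profiles, and a
    synthetic-cohort generator (Hardy-Weinberg genotypes, planted
    two-locus profile, arm-specific exponential survival) so the whole
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
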