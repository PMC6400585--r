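Package: prsatlas
Title: Polygenic Risk Score Phenome Scans with Mendelian Randomization Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building polygenic risk scores (PRS) from GWAS summary
    statistics (LD clumping, proxy substitution, allele harmonization,
    weighted and unweighted scoring), running phenome-wide association scans
    of scores against continuous, binary, ordinal and categorical traits with
    covariate adjustment, and triaging scan hits with two-sample Mendelian
    randomization: IVW, MR-Egger, weighted median and weighted mode
    estimators, Cochran's Q, Steiger directionality filtering, leave-one-out,
    bi-directional MR, mediation MR with proportion mediated, and
    multivariable MR. A synthetic-data module generates genotypes in
    Hardy-Weinberg proportions with configurable LD blocks, two-sample GWAS
    pairs with known causal effects and horizontal pleiotropy, multi-trait
    cohorts and mediation chains, so the whole pipeline is testable without
    external data. Includes the simulation study comparing PRS association
    tests against IVW MR for power and false-positive rate under horizontal
    pleiotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
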