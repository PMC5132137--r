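Package: coffeemr
Title: Mendelian Randomization of Coffee Consumption and Prostate Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a Mendelian randomization analysis
    of coffee consumption and prostate cancer risk and progression in a
    multi-study case-control consortium. Builds a two-SNP genetic risk score
    instrument from imputed allele dosages (rs4410790 in AHR, rs2472297 near
    CYP1A1/2), codes stage, grade, coffee/tea and mortality phenotypes with
    the study's deterministic rules, fits principal-component and study
    adjusted logistic models with cluster-robust (sandwich) errors and
    left-truncated Cox proportional-hazards models on the age timescale with
    Efron tie handling, pools per-study estimates by fixed-effect and
    DerSimonian-Laird random-effects meta-analysis, and provides the
    MR-specific scaling, Wald-ratio and minimal-detectable-odds-ratio power
    computations. Because the underlying consortium data are not public, a
    first-class synthetic-cohort generator emulates the consortium's causal
    and confounding structure so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    survival,
    metafor,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
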