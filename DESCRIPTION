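Package: hypoxiaSTS
Title: Hypoxia Gene-Signature Classification and Survival Validation for
    Soft-Tissue Sarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for a clinically deployable 24-gene
    tumour-hypoxia classifier in soft-tissue sarcoma measured on targeted
    nanoString nCounter assays. Provides RCC lane-file reading and writing,
    lane quality control and count normalisation to a log2 expression
    matrix, coefficient-of-variation screening and geNorm stability
    selection of endogenous control genes, unshrunken-centroid
    classification by shortest Spearman distance on median-centred
    profiles, intra-tumour multi-biopsy concordance, and a survival
    validation battery (Kaplan-Meier, log-rank, Cox proportional hazards
    with a univariable screening rule for multivariable models, Harrell's
    C-index, nested-model likelihood-ratio tests, two-stage false
    discovery rate control, and nomogram-based risk stratification). A
    synthetic-data generator emulates the statistical structure of the
    study cohorts so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
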