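Package: p53repress
Title: Discovery and Validation of a p53-Repressed Gene Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable implementation of a multi-screen pipeline for
    identifying genes repressed in a p53-dependent manner under genotoxic
    stress: ratio-based candidate screens over a microarray time course,
    a multi-tissue mouse irradiation RNA-seq design and a tumor cohort
    split by p53 mutation status; cross-dataset candidate intersection
    through an ortholog map; delta-delta-Ct qPCR quantification with a
    three-stage module-membership classifier (ADR panel, p53 knockdown,
    exogenous p53); strand-aware TSS-window peak enrichment with an exact
    two-sided Fisher test; and median-split Kaplan-Meier/log-rank survival
    analysis. Includes seeded synthetic generators for all five input
    modalities with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
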