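Package: nutrimir
Title: Linking Dietary Nutrient Intake to Circulating miRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline relating estimated dietary intake of
    natural compounds (nutrients derived from food-frequency
    questionnaires) to circulating plasma microRNA expression measured
    by small RNA sequencing. Provides nutrient-intake estimation from
    questionnaire responses and food-composition tables with energy
    normalization, median-of-ratios count normalization with
    detectability filtering, diet-group-stratified Spearman correlation
    screening with a sign-coherence rule, linear-model confirmation
    with a covariate-dominance criterion, negative-binomial
    likelihood-ratio differential expression between high- and
    low-intake subjects, logistic-regression gene-set enrichment of
    miRNA targets, and export of the miRNA-nutrient association
    network. A synthetic-cohort generator with planted, calibrated
    rank associations makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea
Config/testthat/edition: 3
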