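Package: ifnnet
Title: Stimulation-Response Co-Expression Networks, Master Regulators and
    Multi-Omic Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired stimulated/unstimulated immune
    profiling cohorts: empirical-Bayes moderated differential expression on
    baseline-adjusted log expression, weighted co-expression networks with
    topological overlap, module eigengenes, intramodular connectivity and
    permutation preservation statistics, differential network wiring between
    outcome strata, mutual-information regulon inference with data-processing-
    inequality pruning and two-tailed rank-enrichment transcription-factor
    activity scores, out-of-bag-tuned random-forest risk prediction with
    repeated random re-splitting and transfer to external cohorts, and
    supervised multi-block sparse partial-least-squares integration of
    transcript, regulon-activity, cytokine, metabolite and cell-proportion
    blocks. Includes a seeded synthetic-cohort generator that plants
    co-expression modules, group-specific connectivity, driver transcription
    factors and predictive modules so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    nortest,
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
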