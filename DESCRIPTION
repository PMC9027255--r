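Package: hccMarkerPanel
Title: Secretory Biomarker Selection and Serum Panel Diagnostics for
    Multistage Hepatocellular Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and evaluating secretory serum
    biomarkers of hepatocellular carcinoma (HCC) across multistage liver
    disease.  Implements the candidate-selection funnel (coding filter,
    signal-peptide screen, stage-specific Venn exclusion, signature
    intersection, top-K ranking) on staged FPKM expression matrices;
    from-scratch diagnostic statistics (empirical ROC and AUC, DeLong
    confidence intervals and paired AUC comparison, Youden-index cutoff
    selection, full 2x2 diagnostic metric tables); OR-rule multi-marker
    panel evaluation including positive-rate tables by disease stage,
    AFP-negative rescue analysis and exhaustive full-coverage panel
    search; Kaplan-Meier estimation with the two-group log-rank test; and
    a calibrated log-normal synthetic cohort generator that emulates
    multistage serum ELISA cohorts and staged expression matrices for
    end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
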