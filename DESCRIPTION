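Package: oxiburden
Title: Intraoperative Tissue-Oxygenation Desaturation Burdens and
    Postoperative Renal Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel near-infrared spectroscopy
    (NIRS) tissue-oximetry traces recorded during cardiac surgery and for
    relating intraoperative desaturation burdens to postoperative renal
    impairment. Implements baseline extraction (pre-incision window mean),
    bilateral renal-channel averaging, area-under-threshold (AUT)
    desaturation burdens for absolute and baseline-relative thresholds, a
    renal-region-specific differential deoxygenation burden, creatinine-based
    renal-impairment labelling, normality-routed group comparisons, ROC
    analysis with Hanley-McNeil confidence intervals and Youden-index
    cutoffs, a statistical synthetic-cohort generator for validation, and a
    config-driven reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
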