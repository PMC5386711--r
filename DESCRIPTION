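Package: progressionscope
Title: Staged Breast-Cancer Progression Analysis of miRNA Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for discovering early-lost tumor-suppressor
    microRNAs in an ordered multi-stage breast-cancer progression panel
    (normal-like through hyperplasia, atypical hyperplasia, ductal carcinoma
    in situ and invasive carcinoma). Provides stage-transition differential
    statistics and monotone trajectory-group classification, miRNA-mRNA
    integration by hypergeometric target-set enrichment with false discovery
    rate control, median-split Kaplan-Meier survival stratification with the
    log-rank test, CpG promoter-methylation trend summaries, relative qPCR
    quantification arithmetic (2^-ddCt), and a synthetic-data generator with
    planted ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
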