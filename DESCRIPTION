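Package: methylomark
Title: Hypomethylation Biomarker Discovery and Diagnostic Evaluation for
    Paired Tumor-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-methylation biomarker analysis in paired
    tumor-normal cohorts: differential filtering of Illumina 450K-style
    beta-value matrices across two discovery cohorts, delta-delta-Ct
    relative quantification of methylation-specific and reverse-transcription
    qPCR assays with three-class fold-ratio calls, diagnostic evaluation of
    cell-free DNA hypomethylation in plasma (sensitivity, specificity,
    predictive values, exact tests), clinicopathological contingency
    analysis, methylation-expression correlation, and Kaplan-Meier survival
    stratification by methylation call. A synthetic-cohort generator with
    planted truth makes the whole pipeline runnable and testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
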