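Package: panelselect
Title: SVM-RFE-CV Biomarker Panel Selection for Two-Class Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects compact biomarker panels from probe-by-sample expression
    matrices for two-class (cancer vs normal) classification. Implements
    per-probe log-ratio normalization, one-way ANOVA screening with
    Benjamini-Hochberg adjusted p-values and Storey-Tibshirani q-values,
    support-vector-machine recursive feature elimination driven by feature
    weights and error counts summed over leave-one-out cross-validation folds
    (SVM-RFE-CV), enumeration-based panel validation ranked by test-set AUC,
    and a full classification-metric suite (confusion matrix, sensitivity,
    specificity, precision, accuracy, ROC/AUC). A synthetic two-class
    expression-data generator with per-sample random effects makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
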