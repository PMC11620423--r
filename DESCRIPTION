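Package: ramanglu
Title: Glucose-Level Classification from Raman Spectra with Hotspot and
    Baseline Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying glucose concentration levels from Raman
    spectra of glucose solutions. Implements sliding-window variance
    ("hotspot") feature selection, iterative modified polynomial
    (IModPoly / Vancouver Raman Algorithm) fluorescence-background removal,
    a repeated stratified k-fold cross-validation harness with one-vs-rest
    accuracy, specificity, sensitivity and ROC-AUC metrics for Extra Trees,
    Random Forest and Support Vector Machine classifiers, grid-search
    hyperparameter tuning, and a synthetic spectrum simulator emulating
    glucose/deionized-water phantom measurements for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    rlang,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
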