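Package: ecgbioage
Title: Biological Age from Automated 12-Lead ECG Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constructs biological age estimates from tables of automatically
    measured 12-lead electrocardiogram (ECG) parameters and evaluates their
    ability to discriminate mortality. Implements two-step, sex-stratified
    parameter selection under collinearity (an age-correlation screen followed
    by pruning of strongly correlated pairs), a principal-component biological
    age calibrated against chronological age, and the Klemera-Doubal
    estimators with and without chronological-age adjustment. Discrimination
    for all-cause and cardiovascular death is assessed with Mann-Whitney AUCs
    and paired or unpaired DeLong tests, overall and within chronological-age
    categories. A synthetic cohort generator with block-collinear,
    age-loaded parameters and sparse exponential mortality supports testing
    of the full pipeline without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
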