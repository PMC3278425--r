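Package: nuisancer
Title: Removal of Nuisance Variability for Biomarker Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to remove nuisance-covariate variability (age, gender,
    education and similar demographic or clinical measures) from tabular
    classification features before diagnostic classification. Implements
    control-group-referenced linear-regression correction, per-target-subject
    stratification of the training set, and their combination, together with
    the surrounding pipeline: t-test feature pre-selection, SMOTE class
    balancing, stepwise partial-F feature selection, a linear regression
    classifier, repeated shared-split cross-validation with paired
    significance testing, and an exhaustive nuisance-feature-subset search.
    Includes synthetic-data generators that emulate the four canonical
    nuisance-feature interaction types and an ADNI-like hippocampal-volume
    scenario, so the full pipeline can be exercised without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
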