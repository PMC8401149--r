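Package: actifrail
Title: Digital Biomarkers of Physical Frailty from Wearable Activity Features
Version: 0.1.0
Authors@R:
    person("actifrail", "maintainers", email = "maintainers@actifrail.org",
           role = c("aut", "cre"))
Description: Identifies minimal sets of pendant-sensor physical-activity
    features ("digital biomarkers") that discriminate physically frail from
    robust older adults under the Fried phenotype definition. Provides a
    seedable synthetic-cohort generator matched to published per-group feature
    moments and phenotype prevalences, per-feature group comparisons with
    Cohen's d effect sizes, a self-contained binary logistic regression core
    with ROC/AUC and confusion-matrix metrics, fixed-feature-set phenotype
    models, and balanced-bootstrap recursive feature elimination with
    out-of-bag validation, plus a published four-feature fixed-coefficient
    frailty scorer and a command-line pipeline interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
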