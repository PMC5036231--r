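Package: limbertail
Title: Owner-Reported Limber Tail Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control analysis of acute caudal myopathy
    ("limber tail") from owner-reported cohort data: keyword screening of
    free-text illness reports, questionnaire-based case/control
    classification, exact binomial (Clopper-Pearson) intervals, exact
    conditional inference for 2x2 tables (conditional maximum-likelihood
    odds ratios, exact confidence intervals and Fisher tests), logistic
    risk modelling, and a permutation test of sire/dam contribution
    clustering against random cohort samples. Includes a synthetic
    Labrador-cohort generator with a pedigree, a logistic disease model
    with a sire-level random effect, templated free-text reports and tail
    questionnaires, so every pipeline stage can be exercised with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
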