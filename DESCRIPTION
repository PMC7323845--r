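Package: consentbias
Title: Estimating Selection Bias from Voluntary Participation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how non-consent biases experimental measurements in
    studies where observational covariates are available for everyone but
    test outcomes only for consenting participants. Couples a logistic
    consent (propensity) model with proper model-based multiple imputation
    of the non-participants' would-be outcomes, validates the imputations
    against propensity-score-matched and size-matched bootstrap reference
    ensembles drawn from the participants, and reports the bias of
    participant-only means and standard deviations relative to the combined
    population. Includes a synthetic-population generator with known ground
    truth and a false-missingness cross-validation procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
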