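Package: simexsel
Title: Average Treatment Effect Estimation with Error-Prone Confounders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inverse-probability-weighted estimation of the average treatment
    effect when some confounders are measured with additive error and the
    active confounders of the treatment model are unknown. The estimator
    combines simulation-extrapolation (SIMEX) correction of the propensity
    model coefficients with a one-step weighted-L1 (LASSO or SCAD derivative
    weight) selection step tuned by BIC, followed by SIMEX correction at the
    treatment-effect level and bootstrap uncertainty. Includes measurement
    error covariance construction from replicate measurements or reliability
    ratios, synthetic-data generators for multivariate-normal confounder
    designs with three treatment links and two outcome models, and a
    replicate-level simulation harness with variable-selection and
    estimation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
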