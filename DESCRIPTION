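Package: gfemula
Title: Target Trial Emulation with the Parametric G-Formula
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates risks of a time-to-event outcome under sustained
    hypothetical intervention strategies from longitudinal cohort data using
    the parametric g-formula (Monte Carlo standardization), with death
    handled as a competing event. Includes pooled logistic discrete-time
    hazard models, sequential covariate models with a visit (measurement)
    process, dynamic blood-pressure and smoking-cessation strategies,
    person-level bootstrap confidence intervals, natural-course calibration
    diagnostics, covariate-reordering sensitivity analyses, subgroup
    analyses, and a fully specified synthetic cohort generator with known
    counterfactual risks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
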