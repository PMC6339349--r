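Package: crmdose
Title: Design and Conduct of Phase I Dose-Finding Trials with the
    Continual Reassessment Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, conducting and evaluating phase I
    dose-escalation trials with the continual reassessment method (CRM).
    Implements one- and two-parameter dose-toxicity models with
    skeleton-based dose labels, indifference-interval skeleton
    calibration, Bayesian posterior inference by deterministic quadrature
    and two-stage maximum-likelihood inference, dose-escalation decision
    rules with safety constraints and stopping rules, exact operating
    characteristics of the 3+3 design, a nonparametric benchmark design,
    Monte-Carlo evaluation of operating characteristics across
    dose-toxicity scenarios, and exhaustive enumeration of dose
    transition pathways. Ships replays of two published CRM case-study
    trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
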