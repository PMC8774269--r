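Package: trustdisc
Title: Delay and Probability Discounting with Proposers of Varying
    Trustworthiness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how the trustworthiness of a proposer
    changes monetary discounting behavior. Implements the 27-item monetary
    choice questionnaire and a 30-item probability discounting
    questionnaire with hyperbolic indifference values and rank-based
    consistency scoring of binary choices; mixed-model analysis of
    log-discounting parameters and inverse-Gaussian response-time models
    across proposer conditions (treatment and sum contrast codings, type-3
    Wald omnibus tests, estimated marginal means with Bonferroni
    correction); untrustworthy-minus-baseline delta scores; and a
    moderation analysis relating CpG methylation of the oxytocin receptor
    gene to the proposer effect, with pick-a-point conditional effects and
    case-resampling bootstrap confidence intervals. A seeded synthetic
    cohort generator emulates the statistical structure of such studies so
    the full pipeline runs without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans
Config/testthat/edition: 3
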