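Package: pipedose
Title: Dual-Agent Dose Escalation with the Product of Independent Beta
    Probabilities Design
Version: 0.1.0
Authors@R:
    person("PIPE", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian adaptive dose-finding for dual-agent phase I trials
    using a curve-free working model: independent beta priors on the
    dose-limiting-toxicity probability of every dose combination,
    conjugate beta-binomial updating, and enumeration of all monotonic
    maximum-tolerated-contour candidates scored by a product of
    independent beta tail probabilities.  Provides prior elicitation
    from median toxicity grids, escalation policies (closest/adjacent
    admissible doses, dose-skipping and safety constraints, coherence),
    recommended phase II dose selection, a Monte-Carlo simulator for
    operating characteristics, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
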