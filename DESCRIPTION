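Package: acosim
Title: Agent-Based Simulation of Shared-Savings Accountable Care
    Organizations for Heart Failure Care
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A discrete-time agent-based simulator of accountable care
    organization (ACO) demonstrations for congestive heart failure (CHF)
    care in a Medicare 65+ population. Patients progress through a
    CHF-free / CHF-diagnosed / hospitalized / dead state-transition model
    on a 15-day cycle with piecewise-exponential mortality derived from
    published survival curves; hospital and primary-care provider agents
    decide annually whether to deliver a transitional-care intervention
    using a Theory of Planned Behavior model (attitude, subjective norm
    via message passing, perceived behavioral control via discharge
    interactions, softmax choice); a payer agent reimburses
    fee-for-service care and settles a shared-savings contract governed
    by the shared saving rate (SSR) and the sharing rate to hospitals
    (SRH). Includes a synthetic-population generator, a Monte Carlo
    replication harness with confidence intervals, payment-parameter
    sweep and one-at-a-time sensitivity experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
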