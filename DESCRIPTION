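Package: trialops
Title: Participant States, Balanced Randomization, Double-Blind Kit
    Allocation and On-Demand Drug Supply for Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running the operational side of a double-blind
    randomized controlled trial without a commercial trial-management
    system: a participant state machine gating every step of the protocol,
    metabolic-syndrome eligibility screening, covariate-adaptive
    (minimization) randomization with family clustering, pre-generated
    blinded bottle allocation lists in permuted blocks, an expiry-aware
    first-expire-first-out drug warehouse, demand forecasting via the
    (A+B1+B2)-C order formula, an on-demand versus patients'-pack savings
    analysis, and a discrete-event synthetic-trial simulator that exercises
    the whole stack end to end. Includes a file-bundle persistence layer
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
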