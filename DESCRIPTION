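Package: mamsdelay
Title: Efficiency Loss of Multi-Arm Multi-Stage Trials Under Outcome Delay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of group-sequential multi-arm multi-stage
    (MAMS) clinical trials with separate per-arm stopping rules, and
    quantification of the efficiency such designs lose when the primary
    outcome is observed with delay. Provides familywise-error-rate and
    conjunctive-power calibration of efficacy/futility stopping boundaries
    via multivariate normal integration, exact enumeration of trial outcome
    paths and their probabilities, expected sample size with and without
    pipeline participants accrued under uniform or linearly increasing
    recruitment, the efficiency-loss metric relative to a single-stage
    multi-arm design, scenario grids over delay lengths and interim
    spacings, and an independent Monte Carlo trial simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
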