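Package: pedflow
Title: Discrete-Event Simulation and Analysis of Secondary Triage in a
    Pediatric Emergency Department
Version: 0.1.0
Authors@R: person("pedflow", "maintainers", email = "pedflow@example.org",
    role = c("aut", "cre"))
Description: Calibrated discrete-event simulation of patient flow through a
    pediatric emergency department (PED), together with a re-implementation
    of a percentile-based secondary-triage prioritization policy and the
    analysis pipeline of a day-randomized trial.  Stage durations are
    sampled from (zero-inflated) log-normal distributions quantile-matched
    to published median/IQR summaries; arrivals follow a two-piece
    nonhomogeneous Poisson process with a day/night split.  Includes
    median/IQR summaries, ANCOVA arm comparisons adjusted for triage
    priority, standardized differences, census curves with a stratified
    permutation test, Little's-law census planning arithmetic, and System
    Usability Scale (SUS) scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
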