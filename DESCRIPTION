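Package: operantr
Title: Operant Conditioning Schedules, Session Simulation and Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing rodent operant-conditioning
    experiments built around nose-poke chambers: fixed-ratio and
    progressive-ratio reinforcement schedules, a deterministic session state
    machine that applies schedule, timeout and termination rules to
    timestamped poke streams, a plain-text event-log format with per-session
    summaries, task-progression criteria (acquisition, exclusion, breakpoint
    stabilization), a stochastic virtual-mouse simulator for generating
    synthetic genotype cohorts, and the cohort statistics commonly reported
    for such experiments (Welch's t-test, Cohen's d, analytic power for the
    two-sample t-test with unequal group sizes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
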