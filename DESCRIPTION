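Package: stopsignal
Title: Stop-Signal Task Simulation, SSRT Estimation, and Inhibition Expertise Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for response-inhibition psychometrics with the stop-signal
    task. Simulates the task as administered (independent horse-race model with
    an adaptive stop-signal-delay staircase), estimates stop-signal reaction
    time (SSRT) by the integration method, summarises two-choice response times
    and strategic slowing, and provides the inferential layer used in motor
    expertise studies: pooled-variance t tests, standardized mean differences
    with noncentral-t confidence intervals, mixed between-within ANOVA with
    partial eta squared, Fisher-z correlation intervals and comparisons, Bayes
    factors for t tests under default and informed Cauchy priors, and a-priori
    sample size for the 2x2 within-between design. A pipeline runs
    simulate -> estimate -> analyze from a single config with one seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
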