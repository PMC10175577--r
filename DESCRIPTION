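Package: wmtsim
Title: Simulation and Analysis of Adaptive Working Memory Training Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and analysing randomized working memory
    training (WMT) interventions built on adaptive n-back tasks. Provides a
    turn-based engine for staircase-adaptive verbal and spatial n-back blocks,
    scoring for digit-span and timed relational-reasoning transfer tasks, a
    synthetic cohort generator covering distributed and intensive training
    schedules with attrition, learning-curve analysis via one-knot linear
    splines with exhaustive knot search, sequential FDR-corrected session
    contrasts, mixed factorial ANOVAs with partial eta squared, and a
    reproducible simulate-analyse-report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
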