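Package: dualtask
Title: Cognitive-Motor Dual-Task Assessment and Training Engine
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, scriptable engine for cognitive-motor dual-task
    assessment and training in neurorehabilitation (for example, in people
    with multiple sclerosis). Implements generation and scoring of three
    cognitive assessment tasks (titrated backwards digit span, auditory
    vigilance, serial subtraction by seven with carry-forward scoring), a
    19-condition single/dual assessment battery with per-patient
    reproducible ordering, motor and cognitive dual-task cost analytics, an
    11-exercise training catalog with three difficulty levels and a
    good/bad progression state machine, end-of-exercise feedback reports
    with 50%/70% threshold flags, program-level outcome scoring (adherence,
    Borg RPE, the 30-item Intrinsic Motivation Inventory), simulated
    responders for end-to-end testing, and JSON/CSV persistence with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
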