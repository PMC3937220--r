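Package: nflreboot
Title: Negative-Feedback-Loop Reboot Dynamics and Plasmid Invasion Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and measurement analytics for transcriptional networks of
    conjugative plasmids built from negatively autoregulated transcription
    units. Integrates ordinary differential equation models of negative
    feedback loops (simple, dimerization-extended, and two-repressor OR-logic
    variants), computes feedback gain and the transcriptional overshoot that
    follows genome reboot (entry of the replicon into a naive cell with zero
    mRNA and zero regulator), classifies damped versus cyclostationary
    regimes, and lifts single-cell reboot kinetics to population-level bulk
    mRNA fold-changes through an asynchronous conjugative-invasion cohort
    model. Companion analytics cover GFP/OD promoter-activity calling,
    repression-network topology inference, qPCR primer-efficiency filtering,
    threshold-cycle transcriptional landscapes, and growth-normalized
    fold-changes with first-order error propagation. A seeded synthetic-data
    generator emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
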