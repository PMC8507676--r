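Package: edgame
Title: Stochastic Simulator for an Emergency Department Dice Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-round simulation of a cooperative emergency department
    (ED) board game used to teach Goldratt's theory of constraints (TOC).
    Patients flow from walk-in through registration, triage and medical
    assessment to four specialized resources (suture, imaging, lab,
    medication) and back to assessment before discharge; every station's
    per-round capacity is a die roll. The package implements the traditional
    management rules (minimum-batch processing with delayed-care tokens and
    left-without-treatment exits), the TOC counterparts (batch of one,
    GP referral at triage, buffer-management prioritisation at medical
    assessment) and six assessment allocation strategies, plus a seeded
    Monte Carlo driver, summary statistics (throughput, WIP, LWOT, Little's
    Law length of stay), confidence-interval strategy comparison, score-sheet
    and summary-table writers, and scripted-dice replay for deterministic
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
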