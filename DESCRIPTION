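Package: opitaper
Title: Individualized Opioid Taper Schedules and Deprescribing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates individualized, linear opioid dose-reduction
    (deprescribing) schedules from a patient's last-24-hour opioid
    consumption, expressed in oral morphine equivalents (OME). Implements
    acute (25% every other day) and chronic (10% every third day) taper
    presets, discharge grace periods, tiered tapers for chronic users with
    acute pain episodes, back-up (rescue) dose sizing, equianalgesic opioid
    rotation with incomplete cross-tolerance (30/50/100% schemes), mapping of
    exact daily doses onto commercially available tablet strengths, and a
    patient-facing handout renderer. A companion statistics module provides
    Delphi consensus rules, round-to-round test-retest stability (Pearson and
    ICC(A,1)), intercoder percent agreement, the Brennan-Prediger
    chance-corrected agreement coefficient, and Flesch/Amstad readability
    scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
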