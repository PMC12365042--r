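Package: respirhythm
Title: Metabolic Rate Estimation and Circadian Rhythm Analysis for
    Intermittent-Flow Respirometry
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for real-time metabolic biomonitoring of small fish in
    intermittent-flow respirometry chambers.  Estimates oxygen consumption
    (OR), carbon dioxide excretion (CR) and ammonia-nitrogen excretion (AE)
    rates from timestamped sensor traces using weighted finite-difference
    slopes over the sealed measurement window of each flush cycle, derives
    the respiratory and ammonia quotients (RQ, AQ), summarises light/dark
    (photophase/scotophase) contrasts, characterises circadian structure by
    autocorrelation, and clusters diel metabolic profiles with a natively
    implemented self-organizing map followed by Ward's linkage.  A
    calibrated synthetic respirometry simulator reproduces the diel
    structure, group effects and exposure time-courses of a sublethal
    polycyclic aromatic hydrocarbon exposure study in zebrafish, so every
    stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
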