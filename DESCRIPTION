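Package: svmcgame
Title: Game-Based Assessment of Selective Voluntary Motor Control from
    Paired Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for a game-based assessment of selective
    voluntary motor control (SVMC). Paired body-worn accelerometers are
    turned into joint-angle channels via gravity inclination with
    proximal-sensor referencing, the target joint steers an avatar along
    a path calibrated to the player's active range of motion, and two
    standardized-error outcomes are computed against a neurologically
    intact adult reference cohort: target-joint accuracy (deviation from
    the path in adult-SD units) and involuntary movements (non-target
    joint-angle derivatives standardized against the adult mean and SD).
    Age-normalized z-scores use +/- 1 year peer groups. A deterministic
    kinematic simulator generates synthetic sessions with tunable mirror,
    synergy, trunk-sway and tremor impairments, rendered as irregular-rate
    accelerometer streams, so the whole method is testable without
    hardware or patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
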