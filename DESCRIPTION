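Package: spiralmea
Title: Spiral-Wave Detection and Complexity Analysis for High-Density
    Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying and characterising rotating (spiral) and
    planar waves in high-density multi-electrode array (HD-MEA) recordings of
    disinhibited cortical tissue.  Provides zero-phase delta-band filtering,
    artifact removal, 1-ms snapshot extraction, instantaneous-phase and
    vector-field analysis, activity-weighted centre-of-mass estimation,
    winding-number based rotation classification, eigenspectrum and
    participation-ratio complexity measures, Levina-Bickel intrinsic-dimension
    estimation, distance-dependent correlation analysis, and a small
    convolutional generative adversarial network for synthesising activity
    snapshots.  A seeded phenomenological simulator of spiral, planar, and
    baseline HD-MEA activity makes the whole pipeline testable without access
    to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
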