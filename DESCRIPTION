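Package: roomtrack
Title: Room-Level Indoor Localization from Bluetooth Beacon Proximity and
    Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Graph-constrained Bayesian filtering for room-level indoor
    positioning from wrist-worn receivers that log received signal strength
    (RSSI) of fixed Bluetooth low-energy beacons at 10-second epochs.  A
    building is modelled as a graph of grouped areas connected by walking
    pathways; per-epoch transition weights are modulated by accelerometer
    step counts under three a priori motion models; RSSI readings are mapped
    to per-area measurement probabilities and fused by a predict/update
    recursion with exception management (resampling on degenerate
    posteriors, measurement dropouts, anti-hopping smoothing).  Includes a
    jerk-based activity metric with k-means low/middle/high classification,
    an evaluation suite (transition/nontransition error decomposition,
    dwelling-time agreement with ICC and regression fits, confusion
    matrices, lasagna plots), and a synthetic-trial generator emulating
    device-style RSSI, step-count and 100 Hz acceleration exports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
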