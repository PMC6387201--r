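Package: frailhome
Title: Beacon-Based Room-Level Localization and Frailty Assessment from Indoor Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-cost indoor activity monitoring with Bluetooth Low
    Energy beacons. Builds per-room RSSI fingerprints from short training
    walks, converts online RSSI streams into smoothed room-transition logs
    (sliding-window 2-sigma outlier filtering, nearest-fingerprint matching,
    majority-vote label smoothing, outside-the-house detection), and runs the
    downstream frailty-assessment pipeline: dwell-time interval extraction,
    fixed-duration segmentation, mobility feature engineering and stratified
    cross-validated classification into non-frail, pre-frail and frail. A
    synthetic radio-propagation and behaviour simulator (log-distance path
    loss with wall, body and interference effects; semi-Markov room-dwell
    models) replaces the hardware so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    class,
    nnet,
    rpart,
    randomForest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
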