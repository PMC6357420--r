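Package: amapgait
Title: Altered Muscle Activation Pattern Scoring for Gait Electromyography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how a walker's per-muscle surface electromyography
    (EMG) timing and amplitude deviate from a normative profile within six
    biomechanically matched sub-phases of the gait cycle (first double
    support, two halves of single support, second double support, two halves
    of swing). Muscle on/off periods are detected with an exact
    one-dimensional k-means clustering of the linear envelope, gait events
    are derived from vertical ground reaction forces, and deviations are
    expressed as z-scores against a speed-matched healthy cohort, making the
    scores robust to the spatiotemporal asymmetries of hemiparetic gait.
    Includes paretic propulsion computation and a synthetic gait generator
    with analytic ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
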