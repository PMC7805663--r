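Package: beetrackr
Title: Two-Step Learned Tracking of Tagged Honey Bees from Noisy Marker Decodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links noisy, fragmentary per-frame decodings of 12-bit fiducial
    markers on honey bees into long, identity-correct trajectories. A first
    step joins detections in consecutive frames into gapless tracklets using
    a Platt-calibrated linear support vector machine and optimal bipartite
    assignment; a second step merges tracklets across bounded gaps with a
    random forest correspondence classifier. Tracks receive a consensus ID
    by per-bit median voting over the soft bit probabilities of their member
    detections. Includes construction of labeled training samples from
    ground-truth tracks, a naive ID-linking baseline, a perfect-tracking
    bound, a full evaluation suite (incorrect IDs, complete tracks,
    insertions, deletions, mismatches), and a calibrated synthetic colony
    simulator so the whole pipeline is testable without video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr (>= 1.1.0),
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
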