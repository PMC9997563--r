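Package: flywell
Title: Well-Plate Fly Feeding and Locomotion Analysis from Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 96-well Drosophila behavioral assays
    recorded as near-infrared backlit video. Detects single-fly silhouettes
    per well by background-subtraction binarization, connected-component
    labeling and size filtering; computes the per-frame food-interaction
    flag and inter-frame distance and aggregates them into 2-minute
    interval summaries; denoises feeding-bout flag streams with
    run-length gap-closing and short-run removal; compares groups with
    windowed two-sided rank-sum tests under Benjamini-Hochberg adjustment;
    and quantifies dye-based food consumption against linear standard
    curves. Includes a synthetic-session generator with ground-truth
    trajectories so every stage is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
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
    tiff,
    withr
Config/testthat/edition: 3
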