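Package: reverb
Title: Ensemble Decoding and Reactivation Analysis for Event-Aligned Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hippocampal ensemble recordings around brief,
    startling episodic events: peri-event binning and baseline-normalised
    response scores, a three-way unit taxonomy (responsive / selectivity /
    intensity dependence), agglomerative clustering of response profiles,
    regularized multi-class discriminant analysis (MDA) of population
    patterns with cross-validation, sliding-window subspace trajectories and
    detection of post-event pattern reactivations, shuffle-based null
    controls, and pairwise-correlation and explained-variance statistics.
    Includes an inhomogeneous-Poisson spike-train simulator that emulates the
    population structure these analyses assume, so every stage can be
    exercised against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
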