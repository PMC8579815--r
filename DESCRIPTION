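Package: wavekin
Title: Kinematic Analysis of Sequential Upper-Limb Wave Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a body "wave" -- the hip-hop dance move in
    which a vertical displacement pulse travels hand, wrist, elbow, shoulder,
    shoulder, elbow, wrist, hand across the horizontally extended arms --
    is articulated, from raw marker trajectories to cohort statistics.
    Provides a synthetic-trial generator with known ground truth, a plain-text
    trajectory format with explicit missing-sample masks, cubic-spline gap
    repair with an exclusion rule for unresolved dropout, automated
    analysis-window selection, peak-prominence wave segmentation, the standard
    per-trial quality metrics (wave amplitude, wrist-minus-shoulder amplitude,
    residual amplitude and signal-to-noise ratio, sub-movement durations,
    coefficient of variation of propagation speed, shoulder-to-shoulder
    interval), and cohort-level summaries (participant ranking, Pearson and
    Spearman correlation matrices, repeated-measures one-way ANOVA with eta
    squared, quadrant reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
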