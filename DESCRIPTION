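Package: forceseg
Title: Motor Segmentation Analysis of Rapid Isometric Force Pulses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects and quantifies motor segmentation in rapid isometric
    force recordings. Estimates the rate of force development (RFD) and the
    second time derivative of force with windowed least-squares slopes,
    detects force pulses by RFD threshold, counts force segments from
    second-derivative zero crossings, extracts segment and slowing-period
    boundaries, aggregates per-subject medians over randomly selected
    pulses, classifies subjects by segmentation status, and runs the
    cohort-level nonparametric inference layer (exact binomial prevalence
    with Clopper-Pearson intervals, Kruskal-Wallis with Dunn pairwise
    follow-ups and r effect sizes, Mann-Whitney U, tie-corrected Friedman
    tests with step-down homogeneous subsets). Includes a seeded synthetic
    burst-drive cohort simulator with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
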