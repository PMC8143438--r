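Package: ivtrack
Title: Quantitative Analysis of Immune-Cell Interstitial Migration from
    Intravital Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of time-lapse cell tracks
    from multiphoton intravital microscopy of skin. Computes per-track
    motility statistics (mean velocity, displacement, total track length,
    confinement ratio), classifies migratory behaviour into velocity-by-
    confinement quadrants, quantifies cell density and the collagen area
    fraction from second-harmonic-generation image stacks, and compares
    treatment groups with nonparametric rank statistics (Mann-Whitney,
    Kruskal-Wallis with Dunn's post hoc, Holm-Sidak step-down correction).
    Includes a synthetic-experiment generator -- persistent-random-walk
    track cohorts drawn from behavioural phenotype mixtures and fibrous
    collagen-like image volumes with known fill fraction -- so every
    analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
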