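Package: tandemtrap
Title: Spatial Analysis of Tandem-Running Pairs Under Sticky-Surface Entrapment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a preserved two-animal snapshot (for
    example an amber inclusion) records coordinated tandem running. Computes
    body-length-normalised spatial-organisation statistics of paired
    trajectories (inter-individual distance, relative direction, heading
    difference, egocentric density maps, trapped-pair survival counts), builds
    a randomised-pairing null model that breaks inter-individual interaction
    while preserving individual movement via rigid trajectory realignment, and
    classifies leader/follower roles from relative-head-position posture
    features using PCA and logistic regression. Includes a seeded synthetic
    generator of natural and sticky-trapped tandem trajectories and skeleton
    postures for testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
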