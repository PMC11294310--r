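Package: ctiq
Title: Phantom-Based Image Quality Analysis for Photon-Counting CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates digital vessel-phantom CT slices (silicone tubes filled
    with iodine dilutions in water) under reconstruction kernels characterised
    by their modulation transfer function anchors, with dose- and iterative-
    reconstruction-dependent shaped noise, and analyses them with an
    edge-profile chain: background noise estimation, profile amplitude,
    three-point slope curves, transition slope maxima and a 0-8 slope score.
    Includes a factorial sweep runner with tidy outputs, ggplot2 plot helpers,
    and reader-study statistics for ordinal image-quality ratings (paired
    Wilcoxon tests with Bonferroni correction, ordinal Krippendorff's alpha
    with interpretation bands) together with a seeded synthetic Likert-rating
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
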