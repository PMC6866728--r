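Package: vbmtools
Title: Voxel-Based Morphometry, Structural Covariance and Brain-Ageing
    Analysis of Grey-Matter Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise analysis of modulated, smoothed grey-matter density
    volumes: general-linear-model group comparison with permutation-based
    cluster-extent family-wise-error correction, seed-based structural
    covariance mapping with a group-by-covariate interaction test, per-group
    cross-sectional age-slope mapping with thresholded difference maps, and
    region-of-interest association with clinical scores using nearest-visit
    matching.  Includes a reproducible synthetic-cohort generator that plants
    focal atrophy, group-specific age slopes, a seed-anchored covariance
    network and correlated clinical scores, so every stage can be exercised
    and calibrated without access to a clinical imaging repository.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    dplyr,
    tibble,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
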