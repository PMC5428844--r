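Package: stemwalk
Title: Quantitative Analysis of Single and Paired Stem Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lineage-resolved time-lapse trajectories of cultured
    cells, built around the isotropic random-walk description of human
    embryonic stem cell (hESC) migration. Provides a tracks-CSV data model,
    a synthetic trajectory generator (fixed-leg isotropic walks, lognormal
    division times, constant death hazard, post-division cell pairs with
    repel-only or repel-then-attract dynamics), estimators for mean-squared
    displacement, diffusivity, migration speed, step-length isotropy,
    correlation time and directionality, pair kinematics with Type A/B
    classification, and an analytic seeding-density prognostic model for
    clonal colony formation. Tibble-first interfaces with broom-style
    tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
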