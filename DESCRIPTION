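Package: camtrapocc
Title: Single-Season Occupancy Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating site occupancy and detection probability
    from camera-trap surveys of elusive wildlife. Converts timestamped photo
    records and deployment periods into binary detection histories with
    fixed-length survey occasions, standardizes and prunes collinear site
    covariates, fits single-season occupancy models with logit-linked
    covariates on both occupancy and detection by maximum likelihood,
    performs exhaustive AICc model selection with Akaike weights and model
    averaging, assesses fit via parametric-bootstrap Pearson chi-square
    overdispersion checks and k-fold cross-validation, and supports survey
    design through cumulative detection probability curves. Includes a
    calibrated synthetic-data generator emulating a large multi-area
    lowland-tapir camera-trap study, so the full pipeline is testable
    end-to-end without field data.
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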