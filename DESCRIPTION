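Package: phenosync
Title: Environmental Predictability and Interval-Censored Location-Scale
    Models of Parturition Phenology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to relate the timing and synchrony of ungulate
    parturition to environmental predictability. Computes Colwell's
    constancy, contingency and predictability metrics from climate and
    NDVI time series, builds interval-censored birth-date observations
    from estimated fawn ages, fits Gaussian location-scale regressions
    with an interval-censored likelihood and region-by-year random
    intercepts (marginalized by Laplace approximation or adaptive
    Gauss-Hermite quadrature), predicts mean birth date and birth
    synchrony over spatial point grids, and validates predictions
    against independently reported parturition distributions. A
    synthetic-data module generates environmental series and birth
    records from known parameters for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    knitr,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
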