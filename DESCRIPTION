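Package: cityspread
Title: Kernel-Based Modelling of Human-Mediated Pest Spread Across City Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recurrent, kernel-based modelling of long-distance (human-mediated)
    dispersal of invasive urban tree pests across a network of cities, developed
    around the European invasion of the emerald ash borer (Agrilus planipennis).
    Provides great-circle distance networks, single-parameter annual dispersal
    kernels (negative exponential, normal, Cauchy fat-tailed), a complement-product
    yearly recurrence for per-city detection probabilities, least-squares kernel
    calibration against binary presence/absence surveys, survey-based verification,
    multi-year forecasting conditioned on confirmed detections, probability-band
    risk maps with GeoJSON export, and seeded synthetic city networks for
    end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
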