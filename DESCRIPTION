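Package: expocube
Title: Dynamic Food-Environment Exposure Assessment with Environmental
    Context Cubes and Space-Time Tunnels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Time-resolved exposure assessment for environmental health
    studies. Builds environmental context cubes (ECCs), regular
    space-time voxel grids of distance-decayed environmental intensity
    driven by feature opening hours, sweeps individual space-time
    tunnels (ISTTs) along GPS trajectories, and scores each person's
    exposure with the environmental context exposure index (ECEI).
    Includes GPS preprocessing (gap imputation, valid-day and
    valid-participant screening), the four conventional activity-space
    comparators (trajectory buffer, minimum convex polygon, standard
    deviational ellipses), a synthetic-data generator for outlets,
    trajectories and outcomes, and a binary-logistic model-comparison
    harness (AIC, Nagelkerke R-squared, likelihood-ratio chi-square,
    odds ratios).
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
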