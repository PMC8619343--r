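Package: cropsense
Title: Growth-Stage-Aware Data Sensing Strategies for Crop Monitoring Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and evaluates a data-sensing strategy for the entire
    crop lifecycle in clustered sensor networks. Divides growth stages from
    historical growth-index series by Gath-Geva fuzzy clustering with
    partition-validity model selection, predicts the current stage with a
    Takagi-Sugeno fuzzy neural network, ranks environmental parameters by
    variance-weighted grey relational analysis under a sensing-time budget,
    and selects a minimal sensor-node subset under an effective sensing-area
    constraint. Includes a synthetic lifecycle and sensor-field generator,
    all-nodes and partial-nodes baselines, and per-unit data-value metrics.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
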