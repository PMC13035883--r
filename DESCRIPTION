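Package: biasplit
Title: Simulating Realistic Non-IID Client Data Distributions for Federated Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions a pooled, continuously-labeled cohort into
    client-specific subsets whose one- or multi-dimensional label
    distributions match prescribed Gaussian targets, for simulating
    realistic non-IID conditions in federated-learning pre-studies.
    Implements a greedy, multi-restart sampler that minimizes a combined
    cost of per-group chi-squared histogram distances and a squared
    Gini size-imbalance penalty, together with strict-median and random
    IID baseline splitters, a mixture-moment feasibility solver, binned
    Bhattacharyya evaluation, a synthetic anthropometric cohort
    generator with regional demographic presets, and a desk-scale
    federated-averaging demonstrator on toy linear regression tasks.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
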