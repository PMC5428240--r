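Package: beeforage
Title: Learning Performance and Lifetime Foraging Analysis for RFID-Tracked Bumble Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links laboratory visual-learning performance of individual bumble
    bee workers to their lifetime field foraging performance. Fits first-order
    exponential decay learning curves to flower-choice sequences and derives a
    Learning Performance Index (LPI), extracts foraging bouts from RFID
    entry/exit event logs, estimates nectar and pollen collection rates from
    weighing-station observations, and compares candidate mixed-effects models
    (colony as a random intercept) with small-sample-corrected AIC (AICc) to
    test whether learning ability predicts foraging activity and efficiency.
    Includes a seeded synthetic-cohort generator emulating the joint structure
    of choice sequences, tag-read logs and observation records, so the whole
    pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    yaml
Config/testthat/edition: 3
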