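# beeforage

Does being a fast learner make a bumble bee a better forager? `beeforage`
is an R package for analysts of individually tagged social insects that
links **laboratory visual-learning performance** of *Bombus terrestris*
workers to their **lifetime field foraging performance**. It covers the
whole chain from raw data streams to model-selection tables:

* **Learning curves** — fits the first-order decay `y = y0 + A·e^(−x/t)` to
  a bee's errors (blue-flower choices) per 10-choice block, where `x`
  counts choices after the bee first feeds from a yellow flower; derives
  the **Learning Performance Index**, `LPI = Σ_{x ∈ {5,50,100}}
  clamp(y(x), 0, 10) ∈ [0, 30]` (low = fast learner).
* **Bout extraction** — turns RFID entry/exit logs into foraging bouts
  (out-read paired with the next in-read, 2-min loitering floor,
  conservative missed-read repair), classifies foragers (> 5 bouts) and
  computes days foraged, bouts/day and bout duration.
* **Collection rates** — matches weighing-station records to bouts and
  estimates nectar rate `(mean in-mass − mean out-mass) / mean duration`
  (mg/min) and pollen rate `mean ordinal load / mean duration` (score/min),
  each requiring ≥ 3 observed bouts.
* **Inference** — bottom-up candidate-model comparison with colony as a
  random intercept, scored by small-sample corrected AIC,
  `AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`; LPI is declared predictive of a
  response only when adding it to the best candidate drops AICc by more
  than 2. Spearman, one-way ANOVA and Mann-Whitney helpers are included.
* **Synthetic cohorts** — a seeded generator emulating all three raw data
  streams (choice sequences, tag reads, observation records) with the
  effect structure the analysis assumes, so the pipeline is testable
  without field data.

## Worked example

Simulate a full study and ask which responses learning ability predicts:

```r
library(beeforage)

cfg   <- simulation_config(seed = 7)   # 5 colonies, 15-21 bees each
study <- run_study(cfg)

cohort_activity_stats(study$activity)
#> # A tibble: 1 × 5
#>   n_bees n_foragers pct_foragers total_bouts mean_bouts_per_forager
#> 1     93         60         64.5        7804                   130.

study$comparisons$days_foraged
#> Candidate models for days_foraged (poisson_log, n = 60)
#>         model k  AICc delta_AICc  best   estimate       se
#> 1       basic 2 360.2      35.51 FALSE         NA       NA
#> 2  colony_age 3 362.4      37.71 FALSE  0.0113638 0.084236
#> 3  worker_age 3 362.4      37.72 FALSE -0.0008086 0.013258
#> 4 worker_mass 3 355.0      30.35 FALSE  0.0046553 0.001721
#> 5  best + lpi 4 324.7       0.00  TRUE  0.0631592 0.010921
#> LPI predicts days_foraged (best candidate: worker_mass; LPI estimate 0.063 +/- 0.011)
```

The cohort contains 93 tested bees of which 60 became foragers (64.5%),
completing 7804 bouts. Adding LPI to the best one-covariate model of days
foraged drops the AICc by ~30 — far past the ΔAICc > 2 threshold — and the
fitted LPI coefficient (+0.063 ± 0.011 on the log link) recovers the
generating effect of +0.06: each LPI unit (slower learning) multiplies the
expected number of foraging days by e^0.06 ≈ 1.06. The other four responses
(nectar and pollen rates, bouts/day, bout duration) are simulated with no
LPI effect, and the same run rejects LPI for all four. A known-parameter
check of the index itself:

```r
compute_lpi(learning_curve_fit(y0 = 2, A = 6, t = 20))
#> [1] 11.20574          # = Σ (2 + 6 e^{-x/20}) at x = 5, 50, 100
```

See `vignettes/learning-foraging-pipeline.Rmd` for the model details,
generator design and numerical choices, and
`inst/scripts/beeforage-cli.R` for a thin command-line front end
(`simulate`, `fit-learning`, `extract-bouts`, `efficiency`,
`compare-models`) over CSV files.

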