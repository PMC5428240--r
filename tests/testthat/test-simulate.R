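test_that("degenerate latent curves give all-yellow / all-blue sequences", {
  perfect <- list(bee_id = "b1", y0_true = 0, A_true = 0, t_true = 20)
  seq1 <- simulate_choice_sequence(perfect, seed = 1)
  expect_equal(nrow(seq1), 100)
  expect_true(all(seq1$colour == "Y"))

  hopeless <- list(bee_id = "b2", y0_true = 10, A_true = 0, t_true = 20)
  seq2 <- simulate_choice_sequence(hopeless, seed = 1)
  expect_true(all(seq2$colour == "B"))

  bad <- list(bee_id = "b3", y0_true = 6, A_true = 6, t_true = 20)
  expect_error(simulate_choice_sequence(bad),
               class = "beeforage_config_error")
})

test_that("per-choice error fraction matches the decay formula (Monte Carlo)", {
  set.seed(31)
  bee <- list(bee_id = "b1", y0_true = 2, A_true = 6, t_true = 20)
  p5 <- (2 + 6 * exp(-5 / 20)) / 10   # direct evaluation: 0.66728
  hits <- replicate(8000, {
    s <- simulate_choice_sequence(bee, n_choices = 30)
    probe <- which(s$colour == "Y" & s$probed == 1)[1]
    if (is.na(probe) || probe + 5 > 30) NA else s$colour[probe + 5] == "B"
  })
  expect_equal(mean(hits, na.rm = TRUE), p5, tolerance = 0.02 / p5)
})

test_that("cohort sizes, ranges and determinism match the configuration", {
  cfg <- simulation_config(seed = 12)
  cohort <- simulate_cohort(cfg)
  sizes <- table(cohort$bees$colony_id)
  expect_length(sizes, 5)
  expect_true(all(sizes >= 15 & sizes <= 21))
  expect_true(nrow(cohort$bees) >= 75 && nrow(cohort$bees) <= 105)
  expect_true(all(cohort$bees$y0_true >= 0 & cohort$bees$y0_true <= 10))
  expect_true(all(cohort$bees$y0_true + cohort$bees$A_true <= 10))
  expect_true(all(cohort$bees$t_true > 0))

  again <- simulate_cohort(cfg)
  expect_identical(cohort, again)

  one <- simulate_cohort(simulation_config(n_colonies = 1L,
                                           bees_per_colony = c(1L, 1L),
                                           seed = 2))
  expect_equal(nrow(one$bees), 1)
})

test_that("simulated event streams alternate out/in with at most one terminal out", {
  cfg <- simulation_config(seed = 8)
  cohort <- simulate_cohort(cfg)
  bees <- cohort$bees
  bees$lpi <- runif(nrow(bees), 1, 15)
  ev <- simulate_rfid_log(bees, cfg, seed = 9)
  for (df in split(ev, ev$bee_id)) {
    d <- df$direction[order(df$timestamp)]
    expect_true(all(d[seq_along(d) %% 2 == 1] == "out"))
    expect_true(all(d[seq_along(d) %% 2 == 0] == "in"))
    expect_lte(sum(d == "out") - sum(d == "in"), 1)
  }
  expect_identical(ev, simulate_rfid_log(bees, cfg, seed = 9))
})

test_that("the log link gives the closed-form days-foraged ratio", {
  # two groups of bees whose LPI differs by 10: expected ratio e^0.6
  cfg <- simulation_config(seed = 1, nonforager_prob = 0,
                           bouts_sqrt_intercept = 1.6,
                           duration_sqrt_intercept = 4,
                           colony_age_effect_bouts = 0,
                           colony_age_effect_duration = 0,
                           colony_sd_bouts = 1e-9, colony_sd_duration = 1e-9)
  bees <- tibble::tibble(bee_id = sprintf("b%03d", 1:800),
                         colony_id = rep(c("C01", "C02"), 400),
                         colony_age = 12,
                         lpi = rep(c(0, 10), each = 400))
  ev <- simulate_rfid_log(bees, cfg, seed = 41)
  days <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(ev, direction == "out"), bee_id),
    d = dplyr::n_distinct(as.Date(timestamp, tz = "UTC")))
  days <- dplyr::left_join(bees, days, by = "bee_id")
  days$d[is.na(days$d)] <- 0
  ratio <- mean(days$d[days$lpi == 10]) / mean(days$d[days$lpi == 0])
  expect_equal(ratio, exp(0.6), tolerance = 0.08)
})

test_that("a null LPI effect leaves days foraged uncorrelated with LPI", {
  cfg <- simulation_config(seed = 2, lpi_effect = 0, nonforager_prob = 0,
                           bouts_sqrt_intercept = 1.6,
                           duration_sqrt_intercept = 4)
  bees <- tibble::tibble(bee_id = sprintf("b%03d", 1:500),
                         colony_id = "C01", colony_age = 12,
                         lpi = runif(500, 0, 20))
  ev <- simulate_rfid_log(bees, cfg, seed = 3)
  days <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(ev, direction == "out"), bee_id),
    d = dplyr::n_distinct(as.Date(timestamp, tz = "UTC")))
  days <- dplyr::left_join(bees, days, by = "bee_id")
  days$d[is.na(days$d)] <- 0
  expect_lt(abs(cor(days$lpi, days$d)), 0.12)
})

test_that("the consecutive-day fraction is honoured", {
  cfg <- simulation_config(seed = 4, nonforager_prob = 0,
                           bouts_sqrt_intercept = 1.4,
                           duration_sqrt_intercept = 4)
  bees <- tibble::tibble(bee_id = sprintf("b%04d", 1:1000),
                         colony_id = rep(c("C01", "C02"), 500),
                         colony_age = 12, lpi = 8)
  ev <- simulate_rfid_log(bees, cfg, seed = 5)
  bouts <- extract_bouts(suppressMessages(clean_events(ev)))
  act <- summarize_activity(bouts, bees)
  multi <- act[!is.na(act$consecutive_days) & act$days_foraged >= 2, ]
  expect_equal(mean(multi$consecutive_days), 0.92, tolerance = 0.03 / 0.92)
})

test_that("observation sampling matches the configured fraction", {
  bouts <- make_bouts(rep(45, 20))
  cfg1 <- simulation_config(seed = 1, observation_fraction = 1)
  obs <- simulate_observations(bouts, cfg1, seed = 6)
  expect_equal(nrow(obs), 40)  # one outgoing + one incoming per bout
  expect_equal(sum(obs$direction == "out"), 20)

  # binomial expectation at the study's observed fraction
  big <- purrr::map_dfr(1:47, function(i) make_bouts(rep(40, 98 + (i %% 3)),
                                                     bee_id = sprintf("f%02d", i)))
  big <- big[1:4619, ]
  cfg2 <- simulation_config(seed = 1)
  obs2 <- simulate_observations(big, cfg2, seed = 7)
  n_obs <- nrow(obs2) / 2
  expected <- 4619 * 0.094
  sd2 <- sqrt(4619 * 0.094 * 0.906)
  expect_lt(abs(n_obs - expected), 2 * sd2)

  empty <- simulate_observations(bouts[0, ], cfg2)
  expect_equal(nrow(empty), 0)
})

test_that("incoming mass is outgoing mass plus the nectar load", {
  bouts <- make_bouts(rep(50, 6))
  cfg <- simulation_config(seed = 1, observation_fraction = 1, pollen_prob = 0,
                           nectar_load_mean = 50, nectar_load_sd = 1e-9,
                           mass_noise_sd = 1e-9)
  obs <- simulate_observations(bouts, cfg, seed = 8)
  gain <- obs$mass_mg[obs$direction == "in"] - obs$mass_mg[obs$direction == "out"]
  expect_equal(gain, rep(50, 6), tolerance = 1e-2)
  expect_true(all(obs$pollen_load == "none"))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(observation_fraction = 1.4),
               class = "beeforage_config_error")
  expect_error(simulation_config(bees_per_colony = c(5, 2)),
               class = "beeforage_config_error")
  expect_error(simulation_config(t_sdlog = -1),
               class = "beeforage_config_error")
})
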