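#' Simulate an RFID tag-read event log for a cohort
#'
#' For each bee carrying an LPI value, draws a days-foraged count `D` from a
#' Poisson distribution with `log E[D] = activity_intercept + lpi_effect *
#' LPI`, draws per-day bout counts and bout durations whose square-root scale
#' means depend linearly on colony age, lays the bouts out without overlap
#' inside each day's foraging window, and emits the corresponding alternating
#' out/in tag reads. A configurable fraction of bees (and any bee with
#' `D = 0`) leaves the colony once and never returns, contributing a single
#' unmatched "out" read.
#'
#' @param bees tibble with `bee_id`, `colony_id`, `colony_age` and `lpi`
#'   (typically the cohort table joined with [score_cohort()] output); bees
#'   with missing `lpi` are dropped with a message.
#' @param config a [simulation_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return tibble with `bee_id`, `timestamp` (POSIXct, UTC) and `direction`
#'   (`"out"`/`"in"`), sorted by bee and time.
#' @export
simulate_rfid_log <- function(bees, config = simulation_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  if (anyNA(bees$lpi)) {
    inform(sprintf("dropping %d bees without an LPI (unfittable sequences)",
                   sum(is.na(bees$lpi))))
    bees <- bees[!is.na(bees$lpi), ]
  }
  colonies <- unique(bees$colony_id)
  col_re_b <- setNames(rnorm(length(colonies), 0, config$colony_sd_bouts),
                       colonies)
  col_re_d <- setNames(rnorm(length(colonies), 0, config$colony_sd_duration),
                       colonies)
  sqrt_mean <- function(intercept, slope, age, re) {
    m <- intercept + slope * (age - config$colony_age_ref) + re
    if (any(m < config$sqrt_floor)) {
      warn("derived square-root scale mean below floor; clipping")
      m <- pmax(m, config$sqrt_floor)
    }
    m
  }
  origin <- as.numeric(config$cohort_start)
  per_bee <- lapply(seq_len(nrow(bees)), function(i) {
    bee <- bees[i, ]
    d <- rpois(1L, exp(config$activity_intercept + config$lpi_effect * bee$lpi))
    nonforager <- runif(1) < config$nonforager_prob || d == 0L
    first_day <- sample(0:9, 1L)
    if (nonforager) {
      ts <- origin + first_day * 86400 +
        (config$day_start_min + runif(1, 0, config$day_length_min)) * 60
      return(list(bee_id = bee$bee_id, ts = round(ts), dir = "out"))
    }
    mb <- sqrt_mean(config$bouts_sqrt_intercept, config$colony_age_effect_bouts,
                    bee$colony_age, col_re_b[[bee$colony_id]])^2
    md <- sqrt_mean(config$duration_sqrt_intercept,
                    config$colony_age_effect_duration,
                    bee$colony_age, col_re_d[[bee$colony_id]])^2
    # foraging dates: unbroken run for most bees, otherwise one gap
    day_gaps <- rep(1L, max(d - 1L, 0L))
    if (d > 1L && runif(1) > config$consecutive_fraction) {
      day_gaps[sample(length(day_gaps), 1L)] <- sample(2:4, 1L)
    }
    days <- first_day + cumsum(c(0L, day_gaps))
    ts <- lapply(days, function(dd) {
      n_b <- max(1L, rpois(1L, mb))
      start0 <- origin + dd * 86400 + config$day_start_min * 60 +
        runif(1, 0, 30) * 60
      day_end <- origin + dd * 86400 +
        (config$day_start_min + config$day_length_min) * 60
      durs <- rlnorm(n_b, log(md) - config$duration_sdlog^2 / 2,
                     config$duration_sdlog) * 60
      gap <- runif(n_b, 1, 6) * 60
      starts <- start0 + c(0, cumsum(durs[-n_b] + gap[-n_b]))
      ends <- starts + durs
      keep <- ends <= day_end        # overflow bouts form a suffix; drop them
      rbind(starts[keep], ends[keep])
    })
    ts <- round(unlist(ts))          # columns interleave out/in per bout
    list(bee_id = bee$bee_id, ts = ts,
         dir = rep(c("out", "in"), length(ts) / 2))
  })
  out <- tibble::tibble(
    bee_id = rep(vapply(per_bee, `[[`, character(1), "bee_id"),
                 vapply(per_bee, function(b) length(b$ts), integer(1))),
    timestamp = as.POSIXct(unlist(lapply(per_bee, `[[`, "ts")),
                           tz = "UTC", origin = "1970-01-01"),
    direction = unlist(lapply(per_bee, `[[`, "dir"))
  )
  dplyr::arrange(out, .data$bee_id, .data$timestamp)
}

#' Simulate weighing-station observation records for a set of bouts
#'
#' Samples a fraction of the supplied bouts for observation. Every observed
#' bout yields an outgoing record (body mass from the configured mass model)
#' and an incoming record: nectar bouts come home heavier by the nectar crop
#' load, pollen bouts carry a pollen-load category drawn uniformly from
#' small/medium/large/very_large. Record timestamps are jittered around the
#' bout start/end within the downstream matching tolerance.
#'
#' @param bouts tibble from [extract_bouts()] (needs `bee_id`, `start`,
#'   `end`).
#' @param config a [simulation_config()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return tibble with `bee_id`, `timestamp`, `direction`, `mass_mg`,
#'   `pollen_load` (one of none/small/medium/large/very_large).
#' @export
simulate_observations <- function(bouts, config = simulation_config(),
                                  seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  if (nrow(bouts) == 0) {
    return(tibble::tibble(bee_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          direction = character(), mass_mg = numeric(),
                          pollen_load = character()))
  }
  observed <- rbinom(nrow(bouts), 1L, config$observation_fraction) == 1L
  obs <- bouts[observed, ]
  if (nrow(obs) == 0) return(simulate_observations(bouts[0, ], config))
  is_pollen <- runif(nrow(obs)) < config$pollen_prob
  out_mass <- rnorm(nrow(obs), config$outgoing_mass_mean,
                    config$outgoing_mass_sd)
  gain <- ifelse(is_pollen,
                 abs(rnorm(nrow(obs), 15, 5)),
                 rnorm(nrow(obs), config$nectar_load_mean,
                       config$nectar_load_sd))
  load_cat <- ifelse(is_pollen,
                     sample(c("small", "medium", "large", "very_large"),
                            nrow(obs), replace = TRUE),
                     "none")
  jitter_s <- function(n) runif(n, -60, 60)
  out_rec <- tibble::tibble(
    bee_id = obs$bee_id,
    timestamp = obs$start + round(jitter_s(nrow(obs))),
    direction = "out",
    mass_mg = round(out_mass + rnorm(nrow(obs), 0, config$mass_noise_sd), 1),
    pollen_load = "none"
  )
  in_rec <- tibble::tibble(
    bee_id = obs$bee_id,
    timestamp = obs$end + round(jitter_s(nrow(obs))),
    direction = "in",
    mass_mg = round(out_mass + gain + rnorm(nrow(obs), 0, config$mass_noise_sd), 1),
    pollen_load = load_cat
  )
  dplyr::arrange(dplyr::bind_rows(out_rec, in_rec), .data$bee_id,
                 .data$timestamp)
}

#' Write a simulated cohort to a directory of CSV files
#'
#' Writes `bees.csv`, `choices.csv`, `events.csv` and `observations.csv` in
#' the package's standard schemas (timestamps as ISO 8601 UTC strings).
#'
#' @param cohort list as produced inside [run_study()]: needs `bees`,
#'   `choices`, `events`, `observations`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(cohort$bees[, c("bee_id", "colony_id", "worker_age",
                                   "worker_mass", "colony_age")],
                   file.path(dir, "bees.csv"))
  readr::write_csv(cohort$choices, file.path(dir, "choices.csv"))
  ev <- cohort$events; ev$timestamp <- iso(ev$timestamp)
  readr::write_csv(ev, file.path(dir, "events.csv"))
  ob <- cohort$observations; ob$timestamp <- iso(ob$timestamp)
  readr::write_csv(ob, file.path(dir, "observations.csv"))
  invisible(dir)
}

#' Read the pipeline's standard CSV inputs
#'
#' Readers for the four delimited input tables (`bees.csv`, `choices.csv`,
#' `events.csv`, `observations.csv`). Timestamps are parsed as ISO 8601 UTC.
#'
#' @param path file path.
#' @return a tibble in the corresponding schema.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          bee_id = readr::col_character(),
                          timestamp = readr::col_datetime(),
                          direction = readr::col_character()))
  ev
}

#' @rdname read_tables
#' @export
read_observations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bee_id = readr::col_character(),
                    timestamp = readr::col_datetime(),
                    direction = readr::col_character(),
                    mass_mg = readr::col_double(),
                    pollen_load = readr::col_character()))
}

#' @rdname read_tables
#' @export
read_choices <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    bee_id = readr::col_character(),
                    visit_index = readr::col_integer(),
                    colour = readr::col_character(),
                    probed = readr::col_integer()))
}

#' @rdname read_tables
#' @export
read_bees <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(bee_id = readr::col_character(),
                                          colony_id = readr::col_character()))
}
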