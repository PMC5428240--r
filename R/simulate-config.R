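#' Configuration for the synthetic bumble bee cohort generator
#'
#' Builds and validates the parameter set that drives every synthetic-data
#' generator in the package. Defaults reproduce the structure of the study
#' cohort the pipeline was designed around: five colonies of 15--21 tested
#' workers, latent learning curves whose per-bin error counts stay in
#' \[0, 10\] by construction, a positive LPI effect (+0.06 per LPI unit) on
#' log days foraged, colony-age effects of -0.52 and +0.06 on the square-root
#' scales of bouts per day and bout duration, 9.4% of bouts observed at the
#' weighing station, and 42% of tagged bees that leave once and never return.
#'
#' @param n_colonies number of colonies.
#' @param bees_per_colony integer range (low, high); the number of tested bees
#'   per colony is drawn uniformly from this range.
#' @param seed integer seed making every generator output reproducible.
#' @param n_choices choices recorded per bee in the learning assay.
#' @param y0_shape Beta shape parameters for `y0_true / 10` (saturation error
#'   level, errors per 10-choice bin).
#' @param amp_shape Beta shape parameters for `A_true / (10 - y0_true)` (curve
#'   amplitude as a fraction of the available headroom, so `y0 + A <= 10`).
#' @param t_meanlog,t_sdlog log-normal parameters of the decay constant
#'   `t_true` (choices).
#' @param activity_intercept baseline log expected days foraged at LPI 0.
#' @param lpi_effect per-LPI-unit effect on log expected days foraged.
#' @param nonforager_prob probability a tagged bee leaves the colony once and
#'   never returns (zero-inflation of the days-foraged count).
#' @param colony_age_range integer range (days) of colony age at transfer;
#'   one age is drawn per colony.
#' @param colony_age_ref reference colony age (days) at which the square-root
#'   scale intercepts below apply.
#' @param bouts_sqrt_intercept mean of sqrt(bouts per day) at the reference
#'   colony age.
#' @param colony_age_effect_bouts per-day colony-age effect on sqrt(bouts/day).
#' @param duration_sqrt_intercept mean of sqrt(bout duration in minutes) at
#'   the reference colony age.
#' @param colony_age_effect_duration per-day colony-age effect on
#'   sqrt(duration).
#' @param duration_sdlog log-scale SD of individual bout durations around the
#'   bee's mean.
#' @param colony_sd_bouts,colony_sd_duration between-colony random-intercept
#'   SDs on the respective square-root scales.
#' @param consecutive_fraction fraction of foragers whose foraging dates form
#'   an unbroken run of consecutive days.
#' @param observation_fraction fraction of bouts observed at the weighing
#'   station.
#' @param outgoing_mass_mean,outgoing_mass_sd body mass (mg) model for
#'   outgoing weighings.
#' @param nectar_load_mean,nectar_load_sd nectar crop load (mg) carried home
#'   on a nectar bout.
#' @param mass_noise_sd balance measurement noise SD (mg).
#' @param pollen_prob probability an observed bout is a pollen bout.
#' @param worker_age_range integer range (days) of worker age at testing.
#' @param worker_mass_mean,worker_mass_sd worker body mass (mg) distribution.
#' @param sqrt_floor floor applied to derived square-root scale means; means
#'   clipped here trigger a warning.
#' @param day_start_min minute-of-day at which foraging can start.
#' @param day_length_min length (minutes) of the daily foraging window.
#' @param cohort_start POSIXct origin of the simulated timestamps.
#'
#' @return a list of class `bee_sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 42)
#' cohort <- simulate_cohort(cfg)
#' nrow(cohort$bees)
simulation_config <- function(n_colonies = 5L,
                              bees_per_colony = c(15L, 21L),
                              seed = 1L,
                              n_choices = 100L,
                              y0_shape = c(1.5, 6),
                              amp_shape = c(5, 2),
                              t_meanlog = log(20),
                              t_sdlog = 0.5,
                              activity_intercept = 1.6,
                              lpi_effect = 0.06,
                              nonforager_prob = 0.42,
                              colony_age_range = c(10L, 14L),
                              colony_age_ref = 12,
                              bouts_sqrt_intercept = 3.4,
                              colony_age_effect_bouts = -0.52,
                              duration_sqrt_intercept = 6.5,
                              colony_age_effect_duration = 0.06,
                              duration_sdlog = 0.35,
                              colony_sd_bouts = 0.1,
                              colony_sd_duration = 0.15,
                              consecutive_fraction = 0.92,
                              observation_fraction = 0.094,
                              outgoing_mass_mean = 180,
                              outgoing_mass_sd = 15,
                              nectar_load_mean = 50,
                              nectar_load_sd = 10,
                              mass_noise_sd = 2,
                              pollen_prob = 1 / 3,
                              worker_age_range = c(3L, 12L),
                              worker_mass_mean = 180,
                              worker_mass_sd = 25,
                              sqrt_floor = 0.5,
                              day_start_min = 330,
                              day_length_min = 900,
                              cohort_start = as.POSIXct("2016-07-01 00:00:00",
                                                        tz = "UTC")) {
  cfg <- as.list(environment())
  class(cfg) <- "bee_sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_prob <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", name, "` must be a probability in [0, 1]"),
            class = "beeforage_config_error")
    }
  }
  chk_pos <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(is.na(v)) || any(v <= 0)) {
      abort(paste0("`", name, "` must be positive"),
            class = "beeforage_config_error")
    }
  }
  chk_range <- function(name) {
    v <- cfg[[name]]
    if (length(v) != 2 || any(is.na(v)) || v[1] > v[2] || v[1] < 1) {
      abort(paste0("`", name, "` must be an increasing positive range"),
            class = "beeforage_config_error")
    }
  }
  for (p in c("nonforager_prob", "consecutive_fraction",
              "observation_fraction", "pollen_prob")) chk_prob(p)
  for (p in c("n_colonies", "n_choices", "y0_shape", "amp_shape", "t_sdlog",
              "duration_sdlog", "outgoing_mass_sd", "nectar_load_sd",
              "worker_mass_sd", "outgoing_mass_mean", "nectar_load_mean",
              "worker_mass_mean", "sqrt_floor", "day_length_min")) chk_pos(p)
  for (p in c("bees_per_colony", "colony_age_range", "worker_age_range")) {
    chk_range(p)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    abort("`seed` must be a single integer", class = "beeforage_config_error")
  }
  invisible(cfg)
}
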