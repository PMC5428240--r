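#' Simulate one bee's flower-choice sequence
#'
#' Generates an ordered sequence of `n_choices` flower visits (blue = error,
#' yellow = correct) for a bee with latent decay-curve parameters
#' `(y0_true, A_true, t_true)`. The per-choice error probability at aligned
#' index `x` (the number of choices made after the bee first feeds from a
#' yellow flower) is `clamp((y0_true + A_true * exp(-x / t_true)) / 10, 0, 1)`.
#' Visits before the first yellow probe are drawn at the curve's starting
#' error probability; a bee whose starting probability is 1 never probes a
#' yellow flower and yields an all-blue (unfittable) sequence.
#'
#' @param bee one-row data frame (or list) with `bee_id`, `y0_true`, `A_true`,
#'   `t_true`.
#' @param n_choices total number of recorded visits (>= 10).
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#'
#' @return tibble with columns `bee_id`, `visit_index`, `colour` (`"B"`/`"Y"`)
#'   and `probed` (0/1; yellow visits are fed from, blue visits are rejected).
#' @export
simulate_choice_sequence <- function(bee, n_choices = 100L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  y0 <- bee$y0_true; A <- bee$A_true; t <- bee$t_true
  if (any(is.na(c(y0, A, t))) || y0 < 0 || y0 > 10 || y0 + A > 10 ||
      y0 + A < 0 || t <= 0) {
    abort("invalid latent learning parameters (need y0 in [0,10], y0 + A in [0,10], t > 0)",
          class = "beeforage_config_error")
  }
  if (n_choices < 10) {
    abort("`n_choices` must be >= 10", class = "beeforage_config_error")
  }
  p0 <- choice_error_prob(y0, A, t, 0)
  # pre-probe visits: blue with the curve's starting error probability
  if (p0 >= 1) {
    n_pre <- n_choices
  } else if (p0 <= 0) {
    n_pre <- 0L
  } else {
    n_pre <- min(rgeom(1L, 1 - p0), n_choices)
  }
  colour <- rep("B", n_choices)
  if (n_pre < n_choices) {
    colour[n_pre + 1L] <- "Y"                       # first yellow probe, x = 0
    n_post <- n_choices - n_pre - 1L
    if (n_post > 0) {
      p <- choice_error_prob(y0, A, t, seq_len(n_post))
      colour[(n_pre + 2L):n_choices] <- ifelse(rbinom(n_post, 1L, p) == 1L,
                                               "B", "Y")
    }
  }
  tibble::tibble(
    bee_id = bee$bee_id,
    visit_index = seq_len(n_choices),
    colour = colour,
    probed = as.integer(colour == "Y")
  )
}

#' @importFrom stats rgeom
NULL

#' Simulate a cohort of tested bees and their choice sequences
#'
#' Draws colonies, per-colony sample sizes, bee covariates and latent learning
#' parameters from the configured distributions, then simulates each bee's
#' choice sequence. Latent parameters are drawn so per-bin error counts cannot
#' leave \[0, 10\]: `y0_true` is a scaled Beta on \[0, 10\], `A_true` is a Beta
#' fraction of the remaining headroom `10 - y0_true`, and `t_true` is
#' log-normal.
#'
#' @param config a [simulation_config()].
#' @param seed seed for the draw; defaults to `config$seed`. Pass `NULL` to
#'   use the current RNG stream.
#' @return list with `bees` (tibble: `bee_id`, `colony_id`, `worker_age`,
#'   `worker_mass`, `colony_age`, `y0_true`, `A_true`, `t_true`) and `choices`
#'   (tibble in [simulate_choice_sequence()] format, all bees stacked).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = config$seed) {
  validate_config(config)
  if (!is.null(seed)) withr::local_seed(seed)
  n_per <- sample_range(config$bees_per_colony, config$n_colonies)
  colony_age <- sample_range(config$colony_age_range, config$n_colonies)
  bees <- purrr::map_dfr(seq_len(config$n_colonies), function(j) {
    n <- n_per[j]
    y0 <- 10 * rbeta(n, config$y0_shape[1], config$y0_shape[2])
    A <- (10 - y0) * rbeta(n, config$amp_shape[1], config$amp_shape[2])
    tibble::tibble(
      bee_id = sprintf("C%02dB%02d", j, seq_len(n)),
      colony_id = sprintf("C%02d", j),
      worker_age = sample_range(config$worker_age_range, n),
      worker_mass = round(rnorm(n, config$worker_mass_mean,
                                config$worker_mass_sd), 1),
      colony_age = colony_age[j],
      y0_true = y0,
      A_true = A,
      t_true = rlnorm(n, config$t_meanlog, config$t_sdlog)
    )
  })
  choices <- purrr::map_dfr(seq_len(nrow(bees)), function(i) {
    simulate_choice_sequence(bees[i, ], n_choices = config$n_choices)
  })
  list(bees = bees, choices = choices)
}
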