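#' Merge the per-bee analysis table
#'
#' Joins covariates, learning scores, activity metrics and efficiency
#' records on `bee_id` into the flat table the model comparisons consume.
#'
#' @param bees covariate tibble.
#' @param scores [score_cohort()] output.
#' @param activity [summarize_activity()] output.
#' @param efficiency [efficiency_table()] output.
#' @return tibble, one row per bee.
#' @export
build_bee_table <- function(bees, scores, activity, efficiency) {
  out <- dplyr::left_join(bees,
                          scores[, c("bee_id", "y0", "A", "t", "lpi", "reason")],
                          by = "bee_id")
  act_cols <- setdiff(names(activity), setdiff(names(bees), "bee_id"))
  out <- dplyr::left_join(out, activity[, act_cols], by = "bee_id")
  if (!is.null(efficiency) && nrow(efficiency) > 0) {
    out <- dplyr::left_join(out, efficiency, by = "bee_id")
  } else {
    out$nectar_rate <- NA_real_
    out$pollen_rate <- NA_real_
    out$experience <- NA_integer_
  }
  out
}

#' Run the full synthetic study pipeline
#'
#' Simulates a cohort, scores learning performance, simulates and processes
#' the RFID log and weighing-station observations, merges the per-bee table
#' and (optionally) runs the candidate-model comparison for each response.
#' Everything downstream of the seed is deterministic.
#'
#' @param config a [simulation_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @param responses responses to compare; `NULL` skips inference.
#' @param min_duration minimum bout duration (minutes).
#' @param tolerance observation-matching tolerance (minutes).
#' @return list: `bees`, `choices`, `scores`, `events`, `bouts`, `activity`,
#'   `observations`, `annotated_bouts`, `efficiency`, `bee_table`,
#'   `comparisons` (named list of [compare_candidates()] results).
#' @export
#' @examples
#' \donttest{
#' study <- run_study(simulation_config(seed = 7), responses = "days_foraged")
#' study$comparisons$days_foraged
#' }
run_study <- function(config = simulation_config(), seed = config$seed,
                      responses = c("nectar_rate", "pollen_rate",
                                    "mean_bouts_per_day",
                                    "mean_bout_duration", "days_foraged"),
                      min_duration = 2, tolerance = 2) {
  if (!is.null(seed)) withr::local_seed(seed)
  cohort <- simulate_cohort(config, seed = NULL)
  scores <- suppressMessages(score_cohort(cohort$choices))
  bees <- dplyr::left_join(cohort$bees,
                           scores[, c("bee_id", "lpi")], by = "bee_id")
  events <- suppressMessages(simulate_rfid_log(bees, config))
  cleaned <- suppressMessages(clean_events(events))
  bouts <- extract_bouts(cleaned, min_duration = min_duration)
  activity <- summarize_activity(bouts, cohort$bees)
  observations <- simulate_observations(bouts, config)
  annotated <- suppressMessages(
    match_observations(observations, bouts, tolerance = tolerance))
  efficiency <- efficiency_table(annotated)
  bee_table <- build_bee_table(cohort$bees, scores, activity, efficiency)
  comparisons <- NULL
  if (!is.null(responses)) {
    comparisons <- lapply(stats::setNames(responses, responses), function(r) {
      suppressMessages(compare_candidates(bee_table, r))
    })
  }
  list(bees = cohort$bees, choices = cohort$choices, scores = scores,
       events = events, bouts = bouts, activity = activity,
       observations = observations, annotated_bouts = annotated,
       efficiency = efficiency, bee_table = bee_table,
       comparisons = comparisons)
}
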