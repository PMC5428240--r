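#' Clean a raw RFID event stream
#'
#' Sorts reads per bee by time, collapses exact duplicates (same bee, same
#' second, same direction) and repairs alternation breaks caused by missed
#' reads: two consecutive "out" reads mean the return of the first excursion
#' was missed, so the first "out" is discarded and the later one kept; an
#' "in" read with no preceding "out" is discarded. No durations are imputed.
#' A terminal unmatched "out" (a bee that left and was never read again) is
#' retained so [extract_bouts()] can record it as a censored departure.
#'
#' @param raw tibble with `bee_id`, `timestamp` (POSIXct), `direction`
#'   (`"out"`/`"in"`).
#' @return cleaned event tibble; the number of discarded reads is reported
#'   via a message and stored in the `"n_dropped"` attribute.
#' @export
clean_events <- function(raw) {
  validate_events(raw)
  if (nrow(raw) == 0) return(raw)
  ev <- dplyr::distinct(raw, .data$bee_id, .data$timestamp, .data$direction)
  ev <- dplyr::arrange(ev, .data$bee_id, .data$timestamp,
                       dplyr::desc(.data$direction))  # "out" before "in" at ties
  kept <- purrr::map_dfr(split(ev, ev$bee_id), function(df) {
    keep <- logical(nrow(df))
    pending <- NA_integer_
    for (i in seq_len(nrow(df))) {
      if (df$direction[i] == "out") {
        pending <- i                      # a later "out" supersedes the earlier
      } else {
        if (!is.na(pending)) {
          keep[pending] <- TRUE
          keep[i] <- TRUE
          pending <- NA_integer_
        }                                 # "in" without an "out": drop
      }
    }
    if (!is.na(pending)) keep[pending] <- TRUE   # censored departure
    df[keep, ]
  })
  n_dropped <- nrow(raw) - nrow(kept)
  if (n_dropped > 0) {
    inform(sprintf("clean_events: discarded %d reads (duplicates or incomplete trips)",
                   n_dropped))
  }
  attr(kept, "n_dropped") <- n_dropped
  kept
}

validate_events <- function(ev) {
  need <- c("bee_id", "timestamp", "direction")
  if (!all(need %in% names(ev))) {
    abort("event table needs columns bee_id, timestamp, direction",
          class = "beeforage_validation_error")
  }
  bad_dir <- which(!ev$direction %in% c("out", "in"))
  if (length(bad_dir)) {
    abort(sprintf("invalid direction at row(s) %s",
                  paste(head(bad_dir, 5), collapse = ", ")),
          class = "beeforage_validation_error")
  }
  if (!inherits(ev$timestamp, "POSIXct") || anyNA(ev$timestamp)) {
    bad <- if (inherits(ev$timestamp, "POSIXct")) which(is.na(ev$timestamp)) else seq_len(nrow(ev))
    abort(sprintf("unparseable timestamp at row(s) %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "beeforage_validation_error")
  }
  invisible(ev)
}

#' Extract foraging bouts from a cleaned event stream
#'
#' Pairs each "out" read with the next "in" read of the same bee. Candidate
#' bouts shorter than `min_duration` minutes are treated as nest-entrance
#' loitering and dropped. A terminal unmatched "out" is recorded as a
#' censored departure (in the `"censored_departures"` attribute), not a bout.
#'
#' @param events cleaned event tibble (see [clean_events()]).
#' @param min_duration minimum bout duration, minutes.
#' @return tibble with `bee_id`, `start`, `end`, `duration_min`, `day`
#'   (calendar date of the bout start).
#' @export
extract_bouts <- function(events, min_duration = 2) {
  validate_events(events)
  censored <- list()
  bouts <- purrr::map_dfr(split(events, events$bee_id), function(df) {
    df <- df[order(df$timestamp, df$direction == "in"), ]
    outs <- which(df$direction == "out")
    n_pairs <- min(length(outs), sum(df$direction == "in"))
    if (length(outs) > n_pairs) {
      censored[[df$bee_id[1]]] <<- df$timestamp[outs[length(outs)]]
    }
    if (n_pairs == 0) return(NULL)
    start <- df$timestamp[df$direction == "out"][seq_len(n_pairs)]
    end <- df$timestamp[df$direction == "in"][seq_len(n_pairs)]
    tibble::tibble(bee_id = df$bee_id[1], start = start, end = end)
  })
  if (nrow(bouts) == 0) {
    bouts <- tibble::tibble(bee_id = character(),
                            start = as.POSIXct(character(), tz = "UTC"),
                            end = as.POSIXct(character(), tz = "UTC"))
  }
  bouts$duration_min <- as.numeric(difftime(bouts$end, bouts$start,
                                            units = "mins"))
  bouts <- bouts[bouts$duration_min >= min_duration, ]
  bouts$day <- as.Date(bouts$start, tz = "UTC")
  attr(bouts, "censored_departures") <-
    tibble::tibble(bee_id = names(censored),
                   timestamp = as.POSIXct(unlist(censored), tz = "UTC",
                                          origin = "1970-01-01"))
  bouts
}

#' Per-bee foraging activity summary
#'
#' Computes, for every bee in the covariate table, the three activity
#' metrics used as response variables downstream: number of distinct days
#' foraged, mean bouts per day (total bouts / days foraged) and mean bout
#' duration; classifies foragers (more than five completed bouts) and flags
#' whether the foraging dates form an unbroken consecutive-day run. Bees with
#' no bouts get a zero-count row with missing activity metrics.
#'
#' @param bouts tibble from [extract_bouts()].
#' @param bees bee covariate table (needs `bee_id`; other columns are
#'   carried through).
#' @return tibble: bee covariates plus `n_bouts`, `days_foraged`,
#'   `mean_bouts_per_day`, `mean_bout_duration`, `is_forager`,
#'   `consecutive_days`.
#' @export
summarize_activity <- function(bouts, bees) {
  per_bee <- dplyr::summarise(
    dplyr::group_by(bouts, .data$bee_id),
    n_bouts = dplyr::n(),
    days_foraged = dplyr::n_distinct(.data$day),
    mean_bouts_per_day = dplyr::n() / dplyr::n_distinct(.data$day),
    mean_bout_duration = mean(.data$duration_min),
    consecutive_days = {
      d <- sort(unique(.data$day))
      length(d) == 1 || all(diff(as.integer(d)) == 1)
    },
    .groups = "drop")
  out <- dplyr::left_join(bees, per_bee, by = "bee_id")
  out$n_bouts[is.na(out$n_bouts)] <- 0L
  out$days_foraged[is.na(out$days_foraged)] <- 0L
  out$is_forager <- out$n_bouts > 5
  out
}

#' Cohort-level activity statistics
#'
#' @param activity tibble from [summarize_activity()].
#' @return one-row tibble: `n_bees`, `n_foragers`, `pct_foragers`,
#'   `total_bouts`, `mean_bouts_per_forager`.
#' @export
cohort_activity_stats <- function(activity) {
  tibble::tibble(
    n_bees = nrow(activity),
    n_foragers = sum(activity$is_forager),
    pct_foragers = 100 * mean(activity$is_forager),
    total_bouts = sum(activity$n_bouts),
    mean_bouts_per_forager = mean(activity$n_bouts[activity$is_forager])
  )
}
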