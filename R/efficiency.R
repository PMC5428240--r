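pollen_score_map <- c(small = 1, medium = 2, large = 3, very_large = 4)

#' Match weighing-station records to foraging bouts
#'
#' Attaches each outgoing observation record to the bout of the same bee
#' whose start is nearest in time within the tolerance, and each incoming
#' record to the nearest bout end. Each record attaches to at most one bout
#' and each bout boundary accepts at most one record (records are processed
#' in time order; later contenders are dropped). Ties between equally near
#' bouts go to the earlier bout. Records matching no bout within tolerance
#' are dropped and counted.
#'
#' A bout is *observed* when it has both an outgoing and an incoming record;
#' observed bouts are classified as pollen bouts when the incoming record
#' carries a pollen load, nectar bouts otherwise.
#'
#' @param records observation tibble (`bee_id`, `timestamp`, `direction`,
#'   `mass_mg`, `pollen_load`).
#' @param bouts tibble from [extract_bouts()].
#' @param tolerance matching tolerance, minutes.
#' @return `bouts` with added columns `out_mass`, `in_mass`, `pollen_load`,
#'   `observed`, `resource` (`"nectar"`/`"pollen"`/`NA`); the number of
#'   unmatched records is stored in the `"n_unmatched"` attribute.
#' @export
match_observations <- function(records, bouts, tolerance = 2) {
  validate_observations(records)
  bouts$out_mass <- NA_real_
  bouts$in_mass <- NA_real_
  bouts$pollen_load <- NA_character_
  n_unmatched <- 0L
  records <- records[order(records$bee_id, records$timestamp), ]
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    idx <- which(bouts$bee_id == rec$bee_id)
    if (length(idx) == 0) { n_unmatched <- n_unmatched + 1L; next }
    boundary <- if (rec$direction == "out") bouts$start[idx] else bouts$end[idx]
    dist <- abs(as.numeric(difftime(boundary, rec$timestamp, units = "mins")))
    free <- if (rec$direction == "out") is.na(bouts$out_mass[idx]) else is.na(bouts$in_mass[idx])
    ok <- which(dist <= tolerance & free)
    if (length(ok) == 0) { n_unmatched <- n_unmatched + 1L; next }
    # nearest boundary; ties broken toward the earlier bout (smaller index,
    # bouts being time-ordered within a bee)
    j <- idx[ok[order(dist[ok], ok)[1]]]
    if (rec$direction == "out") {
      bouts$out_mass[j] <- rec$mass_mg
    } else {
      bouts$in_mass[j] <- rec$mass_mg
      bouts$pollen_load[j] <- rec$pollen_load
    }
  }
  if (n_unmatched > 0) {
    inform(sprintf("match_observations: %d records matched no bout within tolerance",
                   n_unmatched))
  }
  bouts$observed <- !is.na(bouts$out_mass) & !is.na(bouts$in_mass)
  bouts$resource <- dplyr::case_when(
    !bouts$observed ~ NA_character_,
    bouts$pollen_load != "none" ~ "pollen",
    TRUE ~ "nectar")
  attr(bouts, "n_unmatched") <- n_unmatched
  bouts
}

validate_observations <- function(records) {
  if (any(records$mass_mg <= 0, na.rm = TRUE)) {
    abort("observation masses must be positive",
          class = "beeforage_validation_error")
  }
  bad <- records$direction == "out" & records$pollen_load != "none"
  if (any(bad, na.rm = TRUE)) {
    abort("outgoing records cannot carry a pollen load",
          class = "beeforage_validation_error")
  }
  if (!all(records$pollen_load %in% c("none", names(pollen_score_map)))) {
    abort("unknown pollen load category",
          class = "beeforage_validation_error")
  }
  invisible(records)
}

#' Nectar collection rate for one bee
#'
#' `(mean incoming mass - mean outgoing mass) / mean bout duration` over the
#' bee's observed nectar (pollen-free) bouts. Requires at least three
#' observed nectar bouts; otherwise the rate is absent (`NA`), not zero. A
#' negative rate (mean incoming below mean outgoing) is reported as-is and
#' flagged via the `"negative"` attribute.
#'
#' @param bee_bouts one bee's annotated bouts ([match_observations()]
#'   output).
#' @param min_bouts minimum number of observed bouts.
#' @return mg per minute, or `NA_real_`.
#' @export
nectar_rate <- function(bee_bouts, min_bouts = 3) {
  nb <- bee_bouts[bee_bouts$observed & bee_bouts$resource == "nectar", ]
  nb <- nb[!is.na(nb$bee_id), ]
  if (nrow(nb) < min_bouts) return(NA_real_)
  rate <- (mean(nb$in_mass) - mean(nb$out_mass)) / mean(nb$duration_min)
  attr(rate, "negative") <- rate < 0
  rate
}

#' Pollen collection rate for one bee
#'
#' Mean ordinal pollen-load score (small = 1, medium = 2, large = 3,
#' very large = 4) over the bee's observed pollen bouts, divided by the mean
#' duration of those bouts. Requires at least three observed pollen bouts.
#'
#' @inheritParams nectar_rate
#' @return pollen score per minute, or `NA_real_`.
#' @export
pollen_rate <- function(bee_bouts, min_bouts = 3) {
  pb <- bee_bouts[bee_bouts$observed & bee_bouts$resource == "pollen", ]
  pb <- pb[!is.na(pb$bee_id), ]
  if (nrow(pb) < min_bouts) return(NA_real_)
  mean(pollen_score_map[pb$pollen_load]) / mean(pb$duration_min)
}

#' Experience covariate
#'
#' Defaults to the total number of completed RFID-recorded bouts; the
#' `"observed"` variant counts only observed bouts of the given resource
#' type.
#'
#' @param bee_bouts one bee's (annotated) bouts.
#' @param variant `"total"` or `"observed"`.
#' @param resource resource type counted under the `"observed"` variant.
#' @return integer count.
#' @export
experience_score <- function(bee_bouts, variant = c("total", "observed"),
                             resource = "nectar") {
  variant <- match.arg(variant)
  if (variant == "total") return(nrow(bee_bouts))
  sum(bee_bouts$observed & !is.na(bee_bouts$resource) &
        bee_bouts$resource == resource)
}

#' Per-bee foraging efficiency table
#'
#' Drives [nectar_rate()], [pollen_rate()] and [experience_score()] over a
#' cohort's annotated bouts.
#'
#' @param annotated bouts annotated by [match_observations()].
#' @param min_bouts minimum observed bouts per resource for a rate.
#' @param experience_variant passed to [experience_score()].
#' @return tibble: `bee_id`, `n_nectar_bouts_observed`,
#'   `n_pollen_bouts_observed`, `nectar_rate`, `nectar_rate_negative`,
#'   `pollen_rate`, `experience`.
#' @export
efficiency_table <- function(annotated, min_bouts = 3,
                             experience_variant = "total") {
  purrr::map_dfr(split(annotated, annotated$bee_id), function(df) {
    nr <- nectar_rate(df, min_bouts = min_bouts)
    tibble::tibble(
      bee_id = df$bee_id[1],
      n_nectar_bouts_observed = sum(df$observed & df$resource == "nectar",
                                    na.rm = TRUE),
      n_pollen_bouts_observed = sum(df$observed & df$resource == "pollen",
                                    na.rm = TRUE),
      nectar_rate = as.numeric(nr),
      nectar_rate_negative = isTRUE(attr(nr, "negative")),
      pollen_rate = pollen_rate(df, min_bouts = min_bouts),
      experience = experience_score(df, variant = experience_variant)
    )
  })
}
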