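# Independent oracles and fixture builders used across the suite.

# Brute-force bout pairing: one literal pass over a bee's raw reads.
# Consecutive "out" reads keep the later one (the earlier excursion lost its
# return read); an "in" with no pending "out" is ignored.
brute_force_bouts <- function(events, min_duration = 2) {
  events <- events[!duplicated(events[, c("bee_id", "timestamp", "direction")]), ]
  out <- list()
  for (id in sort(unique(events$bee_id))) {
    df <- events[events$bee_id == id, ]
    df <- df[order(df$timestamp, df$direction == "in"), ]
    pending <- NA
    for (i in seq_len(nrow(df))) {
      if (df$direction[i] == "out") {
        pending <- df$timestamp[i]
      } else if (!is.na(pending)) {
        dur <- as.numeric(difftime(df$timestamp[i], pending, units = "mins"))
        if (dur >= min_duration) {
          out[[length(out) + 1]] <- data.frame(bee_id = id, start = pending,
                                               end = df$timestamp[i],
                                               duration_min = dur)
        }
        pending <- NA
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(bee_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      duration_min = numeric()))
  }
  do.call(rbind, out)
}

# random raw tag-read stream, deliberately messy: unordered, with duplicate
# reads and alternation breaks
random_event_stream <- function(n_events, n_bees = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- as.POSIXct("2016-07-01 06:00:00", tz = "UTC")
  ev <- data.frame(
    bee_id = sample(sprintf("bee%02d", seq_len(n_bees)), n_events, TRUE),
    timestamp = base + sample(0:36000, n_events, TRUE),
    direction = sample(c("out", "in"), n_events, TRUE)
  )
  # sprinkle exact duplicates
  if (n_events > 4) {
    dup <- ev[sample(n_events, max(1, n_events %/% 10)), ]
    ev <- rbind(ev, dup)
  }
  ev[sample(nrow(ev)), ]
}

# choice tibble for one bee from an explicit post-probe colour string; the
# sequence starts with the first yellow probe itself
choices_from_string <- function(aligned, bee_id = "b1", prefix = character()) {
  cols <- c(prefix, "Y", strsplit(aligned, "")[[1]])
  tibble::tibble(bee_id = bee_id, visit_index = seq_along(cols),
                 colour = cols, probed = as.integer(cols == "Y"))
}

# admissible random latent learning parameters
random_latents <- function(n) {
  y0 <- 10 * rbeta(n, 1.5, 6)
  tibble::tibble(y0 = y0, A = (10 - y0) * rbeta(n, 5, 2),
                 t = exp(rnorm(n, log(20), 0.5)))
}

# a one-bee bout table at given durations (minutes), one bout per hour
make_bouts <- function(durations, bee_id = "b1",
                       start0 = as.POSIXct("2016-07-01 08:00:00", tz = "UTC")) {
  start <- start0 + (seq_along(durations) - 1) * 3600
  tibble::tibble(bee_id = bee_id, start = start,
                 end = start + durations * 60, duration_min = durations,
                 day = as.Date(start, tz = "UTC"))
}
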