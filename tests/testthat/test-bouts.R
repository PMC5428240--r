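mk_events <- function(times, dirs, bee_id = "b1") {
  tibble::tibble(bee_id = bee_id,
                 timestamp = as.POSIXct(times, tz = "UTC"),
                 direction = dirs)
}

test_that("cleaning discards incomplete trips and is idempotent", {
  ev <- mk_events(c("2016-07-01 09:00:00", "2016-07-01 10:00:00",
                    "2016-07-01 10:50:00"), c("out", "out", "in"))
  cleaned <- suppressMessages(clean_events(ev))
  expect_equal(cleaned$direction, c("out", "in"))
  expect_equal(format(cleaned$timestamp[1], "%H:%M"), "10:00")

  ok <- mk_events(c("2016-07-01 09:00:00", "2016-07-01 09:50:00",
                    "2016-07-01 11:00:00", "2016-07-01 11:40:00"),
                  c("out", "in", "out", "in"))
  expect_equal(suppressMessages(clean_events(ok))[, names(ok)], ok,
               ignore_attr = TRUE)

  empty <- ok[0, ]
  expect_equal(nrow(clean_events(empty)), 0)

  # leading "in" with no departure is dropped; duplicates collapsed
  messy <- mk_events(c("2016-07-01 08:00:00", "2016-07-01 09:00:00",
                       "2016-07-01 09:00:00", "2016-07-01 09:50:00"),
                     c("in", "out", "out", "in"))
  expect_equal(suppressMessages(clean_events(messy))$direction, c("out", "in"))
})

test_that("record-level validation pinpoints bad rows", {
  bad_dir <- mk_events(c("2016-07-01 09:00:00"), c("sideways"))
  expect_error(clean_events(bad_dir), class = "beeforage_validation_error")
  bad_ts <- tibble::tibble(bee_id = "b1",
                           timestamp = as.POSIXct(NA, tz = "UTC"),
                           direction = "out")
  expect_error(clean_events(bad_ts), class = "beeforage_validation_error")
})

test_that("bout extraction pairs reads and applies the duration floor", {
  one <- mk_events(c("2016-07-01 09:00:00", "2016-07-01 09:50:00"),
                   c("out", "in"))
  b <- extract_bouts(one)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 50)
  expect_equal(b$day, as.Date("2016-07-01"))

  loiter <- mk_events(c("2016-07-01 09:00:00", "2016-07-01 09:01:00"),
                      c("out", "in"))
  expect_equal(nrow(extract_bouts(loiter)), 0)

  times <- as.POSIXct("2016-07-01 06:00:00", tz = "UTC") + seq(0, by = 1800,
                                                               length.out = 12)
  twelve <- tibble::tibble(bee_id = "b1", timestamp = times,
                           direction = rep(c("out", "in"), 6))
  b12 <- extract_bouts(twelve)
  expect_equal(nrow(b12), 6)
  expect_equal(as.data.frame(b12[, c("bee_id", "start", "end", "duration_min")]),
               brute_force_bouts(twelve), ignore_attr = TRUE)

  censored <- mk_events(c("2016-07-01 09:00:00", "2016-07-01 09:50:00",
                          "2016-07-01 11:00:00"), c("out", "in", "out"))
  bc <- extract_bouts(censored)
  expect_equal(nrow(bc), 1)
  cens <- attr(bc, "censored_departures")
  expect_equal(cens$bee_id, "b1")
})

test_that("activity summary reproduces hand counts and the forager rule", {
  bees <- tibble::tibble(bee_id = c("f6", "f5", "none"))
  d <- as.Date("2016-07-01") + c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3)
  bouts <- tibble::tibble(
    bee_id = c(rep("f6", 10), rep("f5", 5)),
    start = as.POSIXct(paste(c(d, rep("2016-07-10", 5)), "08:00:00"), tz = "UTC") +
      c(seq_len(10), seq_len(5)) * 3600,
    duration_min = c(rep(30, 10), rep(40, 5)))
  bouts$end <- bouts$start + bouts$duration_min * 60
  bouts$day <- as.Date(bouts$start, tz = "UTC")
  act <- summarize_activity(bouts, bees)
  f6 <- act[act$bee_id == "f6", ]
  expect_true(f6$is_forager)        # 10 > 5 bouts
  expect_equal(f6$days_foraged, 3)
  expect_equal(f6$mean_bouts_per_day, 10 / 3)
  expect_equal(f6$mean_bout_duration, 30)
  expect_true(f6$consecutive_days)
  expect_false(act$is_forager[act$bee_id == "f5"])  # exactly 5 bouts
  none <- act[act$bee_id == "none", ]
  expect_equal(none$n_bouts, 0)
  expect_false(none$is_forager)
  expect_true(is.na(none$mean_bout_duration))

  gap <- make_bouts(rep(30, 3))
  gap$day <- as.Date("2016-07-01") + c(0, 1, 3)
  expect_false(summarize_activity(gap, tibble::tibble(bee_id = "b1"))$consecutive_days)
})

test_that("foragers are exactly the bees with six or more bouts", {
  set.seed(61)
  n_bouts <- sample(0:12, 60, replace = TRUE)
  bouts <- purrr::map_dfr(seq_along(n_bouts), function(i) {
    if (n_bouts[i] == 0) return(NULL)
    make_bouts(rep(30, n_bouts[i]), bee_id = sprintf("b%02d", i))
  })
  act <- summarize_activity(bouts, tibble::tibble(bee_id = sprintf("b%02d", 1:60)))
  expect_equal(act$is_forager, n_bouts[match(act$bee_id, sprintf("b%02d", 1:60))] >= 6)
})

test_that("extraction conserves events and durations on random streams", {
  for (s in 1:25) {
    raw <- random_event_stream(sample(5:50, 1), seed = 100 + s)
    cleaned <- suppressMessages(clean_events(raw))
    bouts <- extract_bouts(cleaned, min_duration = 2)
    for (id in unique(raw$bee_id)) {
      bb <- bouts[bouts$bee_id == id, ]
      rr <- raw[raw$bee_id == id, ]
      expect_lte(nrow(bb), sum(rr$direction == "out"))
      if (nrow(bb) > 0) {
        span <- as.numeric(difftime(max(rr$timestamp), min(rr$timestamp),
                                    units = "mins"))
        expect_lte(sum(bb$duration_min), span + 1e-9)
      }
    }
  }
})

test_that("pairing matches the brute-force oracle on random streams", {
  for (s in 1:200) {
    raw <- random_event_stream(sample(2:50, 1), seed = 7000 + s)
    got <- extract_bouts(suppressMessages(clean_events(raw)), min_duration = 2)
    want <- brute_force_bouts(raw, min_duration = 2)
    got <- as.data.frame(got[order(got$bee_id, got$start),
                             c("bee_id", "start", "end", "duration_min")])
    want <- want[order(want$bee_id, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, ignore_attr = TRUE)
  }
})
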