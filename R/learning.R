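#' Align a choice sequence on the first yellow probe and bin the errors
#'
#' Implements the assay's alignment convention: the aligned choice index `x`
#' counts the choices a bee makes after it first feeds from (probes) a yellow
#' flower. Visits up to and including that first probe are dropped, the
#' remaining choices are partitioned into consecutive full bins of
#' `bin_size`, the number of errors (blue choices) is counted per bin, and
#' each bin is placed at its midpoint abscissa `bin_size * i - bin_size / 2`
#' (5, 15, 25, ... for the default bin size of 10). A trailing partial bin is
#' dropped.
#'
#' @param seq_df one bee's choice sequence: tibble with `bee_id`,
#'   `visit_index`, `colour` (`"B"`/`"Y"`), `probed` (0/1).
#' @param bin_size choices per bin.
#' @return tibble with `bee_id`, `bin`, `x_mid`, `errors`, `bin_size`.
#'
#' @section Unfittable sequences: a sequence with no yellow probe, or with
#'   fewer than 3 full bins after alignment (too few points to constrain the
#'   3-parameter decay curve), signals a classed condition
#'   `beeforage_unfittable` whose `reason` field is `"no_probe"` or
#'   `"too_few_bins"`; [score_cohort()] catches it and keeps the bee with a
#'   reason code.
#' @export
align_and_bin <- function(seq_df, bin_size = 10L) {
  stopifnot(is.data.frame(seq_df), bin_size >= 1)
  if (length(unique(seq_df$bee_id)) > 1) {
    abort("`align_and_bin()` takes one bee's sequence at a time")
  }
  seq_df <- seq_df[order(seq_df$visit_index), ]
  probe <- which(seq_df$colour == "Y" & seq_df$probed == 1)[1]
  if (is.na(probe)) {
    abort("sequence has no yellow probe", class = "beeforage_unfittable",
          reason = "no_probe", bee_id = seq_df$bee_id[1])
  }
  aligned <- seq_df$colour[-seq_len(probe)]
  n_bins <- length(aligned) %/% bin_size
  if (n_bins < 3) {
    abort("fewer than 3 full bins after alignment",
          class = "beeforage_unfittable", reason = "too_few_bins",
          bee_id = seq_df$bee_id[1])
  }
  aligned <- aligned[seq_len(n_bins * bin_size)]
  errs <- vapply(seq_len(n_bins), function(i) {
    sum(aligned[((i - 1) * bin_size + 1):(i * bin_size)] == "B")
  }, integer(1))
  tibble::tibble(
    bee_id = seq_df$bee_id[1],
    bin = seq_len(n_bins),
    x_mid = bin_size * seq_len(n_bins) - bin_size / 2,
    errors = errs,
    bin_size = as.integer(bin_size)
  )
}

#' Construct a learning-curve fit object directly
#'
#' Mostly useful for worked examples and downstream calculations where the
#' decay-curve parameters are given rather than estimated.
#'
#' @param y0 saturation error level (errors per bin, in \[0, 10\]).
#' @param A curve amplitude (errors per bin).
#' @param t decay constant (choices, > 0); `NA` is allowed when `A = 0`.
#' @param bee_id identifier.
#' @param converged logical.
#' @param residual_ss residual sum of squares.
#' @return one-row tibble in the [fit_learning_curve()] output schema.
#' @export
#' @examples
#' compute_lpi(learning_curve_fit(y0 = 10, A = 0))  # saturated non-learner: 30
learning_curve_fit <- function(y0, A, t = NA_real_, bee_id = "bee",
                               converged = TRUE, residual_ss = 0) {
  stopifnot(y0 >= 0, y0 <= 10, is.na(t) || t > 0)
  if (A != 0 && is.na(t)) abort("`t` must be given when A != 0")
  tibble::tibble(bee_id = bee_id, y0 = y0, A = A, t = t,
                 converged = converged, residual_ss = residual_ss)
}

#' Fit a first-order decay learning curve to binned errors
#'
#' Least-squares fit of `y = y0 + A * exp(-x / t)` to the per-bin error
#' counts, with box constraints `y0` in \[0, 10\], `A` in \[-10, 10\] and
#' `t` in (0, 10 * n_choices\]. Starting values are `y0 = mean of the last
#' two bins`, `A = first bin - y0`, and `t` from a multi-start grid
#' (20, 5, 80); the best converged start (lowest residual sum of squares)
#' wins. Constant bins are handled without an optimizer: the exact
#' least-squares solution with the smallest |A| is `y0 = c`, `A = 0`, `t`
#' undefined (stored as `NA`). A fit for which no start converges signals
#' `beeforage_unfittable`.
#'
#' @param bins output of [align_and_bin()].
#' @return one-row tibble: `bee_id`, `y0`, `A`, `t`, `converged`,
#'   `residual_ss`.
#' @export
fit_learning_curve <- function(bins) {
  stopifnot(is.data.frame(bins), nrow(bins) >= 3)
  x <- bins$x_mid; y <- bins$errors
  bee <- bins$bee_id[1]
  if (var(y) == 0) {
    return(learning_curve_fit(y0 = y[1], A = 0, t = NA_real_, bee_id = bee))
  }
  t_max <- 10 * (max(x) + bins$bin_size[1] / 2)
  y0_start <- clamp(mean(tail(y, 2)), 0, 10)
  a_start <- clamp(y[1] - y0_start, -10, 10)
  if (a_start == 0) a_start <- 0.5
  best <- NULL
  for (t0 in c(20, 5, 80)) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ y0 + A * exp(-x / t),
        data = data.frame(x = x, y = y),
        start = list(y0 = y0_start, A = a_start, t = min(t0, t_max)),
        lower = c(0, -10, 1e-6), upper = c(10, 10, t_max),
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$convInfo$isConv
    rss <- sum(stats::resid(fit)^2)
    if (ok && (is.null(best) || rss < best$rss)) {
      best <- list(par = coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    abort("learning-curve fit did not converge from any start",
          class = "beeforage_unfittable", reason = "no_convergence",
          bee_id = bee)
  }
  learning_curve_fit(y0 = unname(best$par["y0"]), A = unname(best$par["A"]),
                     t = unname(best$par["t"]), bee_id = bee,
                     residual_ss = best$rss)
}

#' Learning Performance Index
#'
#' Sums the errors predicted by the fitted decay curve after 5, 50 and 100
#' choices, clamping each prediction to the attainable \[0, 10\] errors per
#' 10-choice bin before summation, which bounds the index to \[0, 30\]. Low
#' LPI = fast learner.
#'
#' @param fit one-row fit (from [fit_learning_curve()] or
#'   [learning_curve_fit()]).
#' @param eval_points choice counts at which the curve is evaluated.
#' @return numeric LPI in \[0, 10 * length(eval_points)\].
#' @export
compute_lpi <- function(fit, eval_points = c(5, 50, 100)) {
  if (!isTRUE(fit$converged)) {
    abort("cannot compute LPI from a non-converged fit",
          class = "beeforage_unfittable", reason = "no_convergence",
          bee_id = fit$bee_id)
  }
  pred <- if (fit$A == 0 || is.na(fit$t)) {
    rep(fit$y0, length(eval_points))
  } else {
    fit$y0 + fit$A * exp(-eval_points / fit$t)
  }
  sum(clamp(pred, 0, 10))
}

#' Score a cohort of choice sequences
#'
#' Batch driver: aligns, bins, fits and scores every bee in a stacked choice
#' table. Unfittable bees (no yellow probe, too few bins, or optimizer
#' failure) are retained with `NA` parameters and a reason code so the
#' downstream join can exclude them explicitly.
#'
#' @param choices stacked choice tibble (`bee_id`, `visit_index`, `colour`,
#'   `probed`); visit indices must be unique within a bee.
#' @param bin_size choices per bin.
#' @param eval_points LPI evaluation points.
#' @return tibble: `bee_id`, `y0`, `A`, `t`, `converged`, `residual_ss`,
#'   `lpi`, `reason` (`"ok"` or the unfittable reason).
#' @export
score_cohort <- function(choices, bin_size = 10L, eval_points = c(5, 50, 100)) {
  if (nrow(choices) == 0) {
    return(tibble::tibble(bee_id = character(), y0 = numeric(), A = numeric(),
                          t = numeric(), converged = logical(),
                          residual_ss = numeric(), lpi = numeric(),
                          reason = character()))
  }
  dup <- duplicated(choices[, c("bee_id", "visit_index")])
  if (any(dup)) {
    abort("duplicate (bee_id, visit_index) rows in choice table",
          class = "beeforage_validation_error")
  }
  res <- purrr::map_dfr(split(choices, choices$bee_id), function(df) {
    tryCatch({
      fit <- fit_learning_curve(align_and_bin(df, bin_size = bin_size))
      fit$lpi <- compute_lpi(fit, eval_points = eval_points)
      fit$reason <- "ok"
      fit
    }, beeforage_unfittable = function(cnd) {
      tibble::tibble(bee_id = df$bee_id[1], y0 = NA_real_, A = NA_real_,
                     t = NA_real_, converged = FALSE, residual_ss = NA_real_,
                     lpi = NA_real_, reason = cnd$reason)
    })
  })
  n_bad <- sum(res$reason != "ok")
  inform(sprintf("scored %d bees: %d fitted, %d unfittable",
                 nrow(res), nrow(res) - n_bad, n_bad))
  res[order(res$bee_id), ]
}
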