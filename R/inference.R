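#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k number of estimated parameters (fixed effects, variance
#'   components and any residual variance).
#' @param n sample size; must exceed `k + 1`.
#' @return numeric AICc.
#' @export
#' @examples
#' aicc(-40, k = 3, n = 20)  # 87.5
aicc <- function(log_likelihood, k, n) {
  if (any(n <= k + 1)) {
    abort("AICc undefined: need n > k + 1", class = "beeforage_estimation_error")
  }
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Delta-AICc column of a model comparison table
#'
#' @param aicc_values vector of AICc values (NA allowed for non-converged
#'   candidates).
#' @return `aicc_values - min(aicc_values, na.rm = TRUE)`.
#' @export
delta_aicc <- function(aicc_values) {
  aicc_values - min(aicc_values, na.rm = TRUE)
}

#' Build a model comparison table from names and AICc values
#'
#' Computes the Delta-AICc column against the table minimum and flags the
#' single best model (lowest AICc; ties broken toward fewer parameters, then
#' table order).
#'
#' @param model names character vector.
#' @param aicc_values AICc per model.
#' @param k optional parameter counts, used only for tie-breaking.
#' @return tibble: `model`, `k`, `AICc`, `delta_AICc`, `best`.
#' @export
model_table <- function(model, aicc_values, k = NA_integer_) {
  stopifnot(length(model) == length(aicc_values))
  tab <- tibble::tibble(model = model, k = k, AICc = aicc_values,
                        delta_AICc = delta_aicc(aicc_values))
  ord <- order(tab$AICc, tab$k, seq_len(nrow(tab)))
  tab$best <- FALSE
  tab$best[ord[1]] <- TRUE
  tab
}

# candidate covariate sets and families per response
response_plan <- function(response) {
  plans <- list(
    nectar_rate = list(family = "gaussian_identity",
                       covariates = c("colony_age", "worker_age",
                                      "worker_mass", "experience")),
    pollen_rate = list(family = "gaussian_identity",
                       covariates = c("colony_age", "worker_age",
                                      "worker_mass", "experience")),
    mean_bouts_per_day = list(family = "gaussian_sqrt",
                              covariates = c("colony_age", "worker_age",
                                             "worker_mass")),
    mean_bout_duration = list(family = "gaussian_sqrt",
                              covariates = c("colony_age", "worker_age",
                                             "worker_mass")),
    days_foraged = list(family = "poisson_log",
                        covariates = c("colony_age", "worker_age",
                                       "worker_mass"))
  )
  if (!response %in% names(plans)) {
    abort(sprintf("unknown response '%s'", response),
          class = "beeforage_validation_error")
  }
  plans[[response]]
}

#' Fit one candidate mixed model
#'
#' Maximum-likelihood (not REML) fit of a response on a set of fixed effects
#' plus a colony-level random intercept. `gaussian_sqrt` square-root
#' transforms the response before a linear mixed fit; `poisson_log` fits a
#' Poisson GLMM with log link. The parameter count `k` includes the
#' intercept, the fixed-effect slopes, the random-intercept variance and (for
#' gaussian families) the residual variance. Singular fits (colony variance
#' estimated at zero) are retained with a warning flag; outright
#' non-convergence yields `converged = FALSE` so the candidate can be
#' excluded from comparison.
#'
#' @param data per-bee table containing the response, the covariates and
#'   `colony_id`.
#' @param response response column name.
#' @param fixed_effects character vector of covariate names (may be empty
#'   for the basic, intercept-only model).
#' @param family `"gaussian_identity"`, `"gaussian_sqrt"` or `"poisson_log"`.
#' @return list: `model` (label), `fit`, `log_likelihood`, `k`, `n`, `AICc`,
#'   `estimates` (tibble of term, estimate, se), `converged`, `singular`.
#' @export
fit_candidate <- function(data, response, fixed_effects = character(),
                          family = "gaussian_identity") {
  if (length(unique(data$colony_id)) < 2) {
    abort("need >= 2 colonies to fit a colony random intercept",
          class = "beeforage_estimation_error")
  }
  used <- c(response, fixed_effects, "colony_id")
  if (anyNA(data[, used])) {
    abort("missing values in model columns; subset to complete cases first",
          class = "beeforage_validation_error")
  }
  lhs <- if (family == "gaussian_sqrt") sprintf("sqrt(%s)", response) else response
  rhs <- paste(c("1", fixed_effects, "(1 | colony_id)"), collapse = " + ")
  form <- stats::as.formula(paste(lhs, "~", rhs))
  quiet_fit <- function(ctrl) {
    msgs <- character()
    fit <- withCallingHandlers(
      tryCatch({
        if (family == "poisson_log") {
          lme4::glmer(form, data = data, family = stats::poisson(),
                      control = do.call(lme4::glmerControl, ctrl))
        } else {
          lme4::lmer(form, data = data, REML = FALSE,
                     control = do.call(lme4::lmerControl, ctrl))
        }
      }, error = function(e) e),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    list(fit = fit, msgs = msgs)
  }
  res <- quiet_fit(list())
  bad <- function(r) inherits(r$fit, "error") ||
    any(grepl("failed to converge", r$msgs))
  if (bad(res)) {
    # retry from a more robust derivative-free optimizer before giving up
    res <- quiet_fit(list(optimizer = "bobyqa",
                          optCtrl = list(maxfun = 1e5)))
  }
  fit <- res$fit
  msgs <- res$msgs
  label <- if (length(fixed_effects) == 0) "basic" else paste(fixed_effects, collapse = " + ")
  if (inherits(fit, "error") || any(grepl("failed to converge", msgs))) {
    return(list(model = label, fit = NULL, log_likelihood = NA_real_,
                k = NA_integer_, n = nrow(data), AICc = NA_real_,
                estimates = tibble::tibble(term = character(),
                                           estimate = numeric(),
                                           se = numeric()),
                converged = FALSE, singular = NA))
  }
  ll <- logLik(fit)
  k <- attr(ll, "df")   # fixed effects + RE variance (+ residual variance)
  n <- stats::nobs(fit)
  est <- tibble::tibble(term = names(lme4::fixef(fit)),
                        estimate = unname(lme4::fixef(fit)),
                        se = sqrt(diag(as.matrix(vcov(fit)))))
  list(model = label, fit = fit, log_likelihood = as.numeric(ll),
       k = as.integer(k), n = n, AICc = aicc(as.numeric(ll), k, n),
       estimates = est, converged = TRUE,
       singular = lme4::isSingular(fit))
}

#' Bottom-up AICc candidate-model comparison for one response
#'
#' Fits the basic model (intercept + colony random intercept) and each
#' one-covariate candidate, identifies the best candidate by lowest AICc
#' (ties toward fewer parameters), refits the best candidate with the LPI
#' added, and assembles the comparison table. The verdict is that LPI
#' *predicts* the response when adding it lowers the AICc of the best
#' candidate by more than 2.
#'
#' For `days_foraged` (Poisson) the model is fitted on foragers only; rows
#' with zero days are dropped with a message. Rows with missing values in
#' the response or any candidate covariate are dropped.
#'
#' @param data merged per-bee table (`colony_id`, `lpi`, covariates,
#'   responses).
#' @param response one of `nectar_rate`, `pollen_rate`, `mean_bouts_per_day`,
#'   `mean_bout_duration`, `days_foraged`.
#' @param covariates candidate fixed effects; defaults to the response's
#'   standard candidate set.
#' @return object of class `bee_model_comparison`: list with `response`,
#'   `family`, `table` (model, k, AICc, delta_AICc, best, estimate/se of the
#'   model's own covariate), `fits`, `best_candidate`, `lpi_estimate`,
#'   `lpi_se`, `lpi_verdict` (`"predicts"`/`"does_not_predict"`), `n`.
#' @export
compare_candidates <- function(data, response, covariates = NULL) {
  plan <- response_plan(response)
  if (is.null(covariates)) covariates <- plan$covariates
  used <- c(response, covariates, "lpi", "colony_id")
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    abort(sprintf("data lacks columns: %s", paste(missing_cols, collapse = ", ")),
          class = "beeforage_validation_error")
  }
  dat <- data[stats::complete.cases(data[, used]), ]
  if (response == "days_foraged") {
    n_zero <- sum(dat$days_foraged == 0)
    if (n_zero > 0) {
      inform(sprintf("dropping %d bees with zero foraging days", n_zero))
      dat <- dat[dat$days_foraged > 0, ]
    }
  }
  fits <- c(list(fit_candidate(dat, response, character(), plan$family)),
            lapply(covariates, function(cv) {
              fit_candidate(dat, response, cv, plan$family)
            }))
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) {
    abort("no candidate model converged", class = "beeforage_estimation_error")
  }
  aiccs <- vapply(fits, function(f) f$AICc, numeric(1))
  ks <- vapply(fits, function(f) ifelse(is.na(f$k), Inf, f$k), numeric(1))
  best_i <- order(aiccs, ks, seq_along(fits), na.last = TRUE)[1]
  best <- fits[[best_i]]
  best_covs <- if (best$model == "basic") character() else
    strsplit(best$model, " \\+ ")[[1]]
  lpi_fit <- fit_candidate(dat, response, c(best_covs, "lpi"), plan$family)
  lpi_fit$model <- "best + lpi"
  fits <- c(fits, list(lpi_fit))
  own_est <- function(f) {
    if (!f$converged || nrow(f$estimates) < 2) return(c(NA_real_, NA_real_))
    last <- nrow(f$estimates)
    c(f$estimates$estimate[last], f$estimates$se[last])
  }
  ests <- t(vapply(fits, own_est, numeric(2)))
  tab <- model_table(vapply(fits, function(f) f$model, character(1)),
                     vapply(fits, function(f) f$AICc, numeric(1)),
                     k = vapply(fits, function(f) f$k, integer(1)))
  tab$estimate <- ests[, 1]
  tab$se <- ests[, 2]
  verdict <- if (lpi_fit$converged &&
                 lpi_fit$AICc <= best$AICc - 2) "predicts" else "does_not_predict"
  lpi_row <- match("lpi", lpi_fit$estimates$term)
  structure(list(
    response = response,
    family = plan$family,
    table = tab,
    fits = fits,
    best_candidate = best$model,
    lpi_estimate = if (lpi_fit$converged) lpi_fit$estimates$estimate[lpi_row] else NA_real_,
    lpi_se = if (lpi_fit$converged) lpi_fit$estimates$se[lpi_row] else NA_real_,
    lpi_verdict = verdict,
    n = best$n
  ), class = "bee_model_comparison")
}

#' @export
print.bee_model_comparison <- function(x, ...) {
  cat(sprintf("Candidate models for %s (%s, n = %d)\n",
              x$response, x$family, x$n))
  print(as.data.frame(x$table), digits = 4)
  cat(sprintf("LPI %s %s (best candidate: %s; LPI estimate %.3f +/- %.3f)\n",
              if (x$lpi_verdict == "predicts") "predicts" else "does not predict",
              x$response, x$best_candidate, x$lpi_estimate, x$lpi_se))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list: `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need >= 3 pairs", class = "beeforage_estimation_error")
  if (var(x) == 0 || var(y) == 0) {
    abort("rank correlation undefined for a constant vector",
          class = "beeforage_estimation_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' One-way analysis of variance
#'
#' Classical between/within sums-of-squares decomposition.
#'
#' @param groups list of numeric samples (>= 2 groups, each with >= 2
#'   observations).
#' @return list: `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 observations each",
          class = "beeforage_estimation_error")
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  if (var(y) == 0) {
    # all observations identical: no between-group signal
    return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  }
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' Mann-Whitney U with normal approximation
#'
#' Rank-sum U statistic with average-rank tie handling; z uses the
#' tie-corrected variance, two-sided p from the normal approximation.
#'
#' @param a,b numeric samples.
#' @return list: `U` (minimum of the two U statistics), `z`, `p`.
#' @export
mann_whitney_z <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    abort("both samples must be non-empty",
          class = "beeforage_estimation_error")
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  z <- if (sigma2 == 0) 0 else (u1 - mu) / sqrt(sigma2)
  list(U = min(u1, u2), z = z,
       p = if (sigma2 == 0) 1 else 2 * pnorm(-abs(z)))
}
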