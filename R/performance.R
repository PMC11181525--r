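#' Weighted Kaplan-Meier survival estimate
#'
#' Weighted product-limit estimator with the right-continuous step
#' convention.
#'
#' @param time follow-up times.
#' @param event event indicators (1 = event of interest).
#' @param weights case weights (default 1).
#' @param t evaluation time(s), `>= 0`.
#' @return survival probability at each `t`.
#' @export
km_estimate <- function(time, event, weights = NULL, t) {
  kf <- km_fit(time, event, weights)
  km_eval(kf, t)
}

# Product-limit fit: survival step function at the distinct event times.
km_fit <- function(time, event, weights = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) return(list(times = numeric(0), surv = numeric(0)))
  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]; w <- weights[ord]
  # at-risk weight just before each event time; event weight at that time
  atrisk <- sum(w) - vapply(ut, function(u) sum(w[ts < u]), numeric(1))
  d <- vapply(ut, function(u) sum(w[ts == u & ev == 1]), numeric(1))
  surv <- cumprod(1 - d / atrisk)
  list(times = ut, surv = surv)
}

# Evaluate a km_fit at times t (right-continuous); left = TRUE gives the
# left limit S(t-).
km_eval <- function(kf, t, left = FALSE) {
  if (length(kf$times) == 0L) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, kf$times, left.open = TRUE) else
    findInterval(t, kf$times)
  c(1, kf$surv)[idx + 1L]
}

#' Nagelkerke pseudo R-squared of a Weibull AFT fit
#'
#' `R2 = (1 - exp(-2 (l1 - l0) / n)) / (1 - exp(2 l0 / n))` with `n` the
#' effective sample size (sum of mean-normalized weights); invariant to
#' rescaling all weights by a constant.
#'
#' @param fit a [fit_weibull_aft()] result.
#' @return scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  n <- fit$effective_n
  l1 <- fit$loglik_fitted; l0 <- fit$loglik_null
  den <- 1 - exp(2 * l0 / n)
  if (abs(den) < .Machine$double.eps)
    stopf("degenerate null model: Nagelkerke denominator is zero")
  (1 - exp(-2 * (l1 - l0) / n)) / den
}

# Model survival matrix S(t_g | x_i) for a grid of times: n x length(grid).
model_surv_matrix <- function(fit, cohort, grid) {
  lp <- predict_lp(fit, cohort)
  S <- vapply(grid, function(tg) {
    if (tg <= 0) rep(1, length(lp)) else
      exp(-exp((log(tg) - lp) / fit$sigma))
  }, numeric(length(lp)))
  matrix(S, nrow = length(lp))
}

#' IPCW integrated Brier score
#'
#' Graf-style inverse-probability-of-censoring-weighted Brier score,
#' integrated over the event-time grid up to `tau` (trapezoidal rule,
#' grid augmented with 0 and `tau`, divided by `tau`). The censoring
#' distribution `G` is the weighted Kaplan-Meier estimator with events
#' and censorings swapped; contributions with `G = 0` are dropped (their
#' count is returned in attribute `n_dropped`).
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @param tau integration horizon (default 5).
#' @param use_weights include survey weights in the score (default TRUE).
#' @return scalar IBS with attribute `n_dropped`.
#' @export
integrated_brier_score <- function(fit, cohort, tau = 5, use_weights = TRUE) {
  time <- cohort[[fit$time]]; event <- cohort[[fit$event]]
  w <- if (use_weights) as.numeric(normalize_weights(cohort$weight)) else
    rep(1, nrow(cohort))
  grid <- sort(unique(c(0, time[event == 1 & time <= tau], tau)))
  S <- model_surv_matrix(fit, cohort, grid)
  ibs_core(time, event, w, S, grid, tau)
}

# IPCW Brier machinery on a precomputed model-survival matrix
# S[i, g] = S(grid[g] | x_i); shared by the public wrapper and tests.
ibs_core <- function(time, event, w, S, grid, tau) {
  Gfit <- km_fit(time, 1 - event, w)
  G_at_ti <- km_eval(Gfit, time, left = TRUE)   # G(t_i-)
  G_at_grid <- km_eval(Gfit, grid)
  n_dropped <- 0L
  bs <- vapply(seq_along(grid), function(g) {
    tg <- grid[g]
    died <- time <= tg & event == 1
    alive <- time > tg
    contrib <- numeric(length(time))
    ok_d <- died & G_at_ti > 0
    n_dropped <<- n_dropped + sum(died & G_at_ti <= 0)
    contrib[ok_d] <- S[ok_d, g]^2 / G_at_ti[ok_d]
    if (G_at_grid[g] > 0) {
      contrib[alive] <- (1 - S[alive, g])^2 / G_at_grid[g]
    } else {
      n_dropped <<- n_dropped + sum(alive)
    }
    sum(w * contrib) / sum(w)
  }, numeric(1))
  ibs <- sum(diff(grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / tau
  attr(ibs, "n_dropped") <- n_dropped
  ibs
}

#' Harrell's concordance index
#'
#' Comparable pairs are `(i, j)` with `t_i < t_j` and `delta_i = 1`; a
#' pair is concordant when the predicted risk at the horizon is higher
#' for the earlier failure; ties in predicted risk count 1/2. Pairs are
#' unweighted by default (`use_weights = TRUE` weighs each pair by
#' `w_i w_j`).
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @param horizon risk-prediction horizon (default 5).
#' @param use_weights weighted-pair variant (default FALSE).
#' @return scalar c-index in `[0, 1]`.
#' @export
harrell_c_index <- function(fit, cohort, horizon = 5, use_weights = FALSE) {
  risk <- predict_risk(fit, cohort, horizon)
  concordance_from_risk(cohort[[fit$time]], cohort[[fit$event]], risk,
                        weights = if (use_weights) cohort$weight)
}

# Core pair counting; risk is "higher = earlier failure expected".
concordance_from_risk <- function(time, event, risk, weights = NULL) {
  w <- weights %||% rep(1, length(time))
  ev_idx <- which(event == 1)
  conc <- 0; total <- 0
  for (i in ev_idx) {
    later <- time > time[i]
    if (!any(later)) next
    pw <- w[i] * w[later]
    total <- total + sum(pw)
    conc <- conc + sum(pw * ((risk[later] < risk[i]) +
                               0.5 * (risk[later] == risk[i])))
  }
  if (total == 0) stopf("no comparable pairs")
  conc / total
}

#' Time-specific discrimination slope
#'
#' Difference in weighted mean predicted `t`-year risk between subjects
#' who died by `t` and subjects with event-free follow-up of at least
#' `t`; subjects censored before `t` are excluded (administrative
#' 75th-birthday censoring included, unless
#' `admin_censored_nonevents = TRUE` which treats them as non-events).
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @param t horizon (default 5).
#' @param admin_censored_nonevents treat subjects administratively
#'   censored at the age bound before `t` as non-events (default FALSE).
#' @param max_age age bound used for that reclassification.
#' @return scalar slope.
#' @export
discrimination_slope <- function(fit, cohort, t = 5,
                                 admin_censored_nonevents = FALSE,
                                 max_age = 75) {
  time <- cohort[[fit$time]]; event <- cohort[[fit$event]]
  risk <- predict_risk(fit, cohort, t)
  w <- as.numeric(normalize_weights(cohort$weight))
  admin <- if (admin_censored_nonevents)
    (cohort$age + time >= max_age - 1e-9) else rep(FALSE, length(time))
  ds_core(risk, time, event, w, t, admin)
}

# Status resolution + weighted mean difference; `admin` flags subjects
# whose pre-t censoring should count as a non-event anyway.
ds_core <- function(risk, time, event, w, t, admin = rep(FALSE, length(time))) {
  is_event <- event == 1 & time <= t
  is_nonevent <- time >= t | (event == 0 & time < t & admin)
  if (!any(is_event) || !any(is_nonevent))
    stopf("empty event or non-event group at t = %g", t)
  stats::weighted.mean(risk[is_event], w[is_event]) -
    stats::weighted.mean(risk[is_nonevent], w[is_nonevent])
}

#' Calibration-in-the-large
#'
#' Average observed risk (1 minus the weighted Kaplan-Meier survival at
#' `t` on the whole cohort) minus the weighted mean predicted `t`-risk;
#' negative values indicate overprediction.
#'
#' @inheritParams discrimination_slope
#' @return scalar difference.
#' @export
calibration_in_the_large <- function(fit, cohort, t = 5) {
  w <- as.numeric(normalize_weights(cohort$weight))
  observed <- 1 - km_estimate(cohort[[fit$time]], cohort[[fit$event]], w, t)
  predicted <- stats::weighted.mean(predict_risk(fit, cohort, t), w)
  observed - predicted
}

#' Calibration slope
#'
#' Refits a Weibull AFT model with the frozen linear predictor of `fit`
#' as the sole covariate (own intercept and scale, same weights) and
#' returns the fitted coefficient on the linear predictor; 1 indicates
#' well-scaled coefficients.
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @return scalar slope.
#' @export
calibration_slope <- function(fit, cohort) {
  lp <- predict_lp(fit, cohort)
  if (stats::sd(lp) < 1e-12) stopf("degenerate linear predictor")
  dat <- data.frame(time = cohort[[fit$time]], event = cohort[[fit$event]],
                    lp = lp,
                    .w = as.numeric(normalize_weights(cohort$weight)))
  ctrl <- survival::survreg.control(maxiter = 100, rel.tolerance = 1e-10)
  re <- survival::survreg(survival::Surv(time, event) ~ lp, data = dat,
                          weights = .w, dist = "weibull", control = ctrl)
  unname(stats::coef(re)[2L])
}

#' Decile calibration curve
#'
#' Weighted-quantile bins of predicted `t`-risk; per bin, the weighted
#' Kaplan-Meier observed `t`-risk and the weighted mean predicted risk.
#'
#' @inheritParams discrimination_slope
#' @param n_bins number of risk bins (default 10).
#' @return data.frame of class `calibration_curve` with columns `bin`,
#'   `n`, `mean_predicted`, `observed`, `sum_weight`.
#' @export
calibration_curve <- function(fit, cohort, t = 5, n_bins = 10) {
  stopifnot(n_bins >= 2)
  risk <- predict_risk(fit, cohort, t)
  w <- as.numeric(normalize_weights(cohort$weight))
  edges <- weighted_quantile(risk, w, seq(0, 1, length.out = n_bins + 1))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  edges <- unique(edges)
  if (length(edges) - 1L < n_bins)
    warning("fewer distinct risk values than requested bins: bins merged")
  bin <- cut(risk, edges, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    obs <- 1 - km_estimate(cohort[[fit$time]][sel], cohort[[fit$event]][sel],
                           w[sel], t)
    data.frame(bin = b, n = sum(sel),
               mean_predicted = stats::weighted.mean(risk[sel], w[sel]),
               observed = obs, sum_weight = sum(w[sel]))
  }))
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' All six performance measures for one fitted model on one cohort
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @param horizon evaluation horizon for the time-specific measures and
#'   the Brier integration limit (default 5 years).
#' @return list of class `performance_report` with elements
#'   `nagelkerke_r2`, `integrated_brier`, `c_index`,
#'   `discrimination_slope`, `calibration_in_the_large`,
#'   `calibration_slope`, `horizon`.
#' @export
performance_report <- function(fit, cohort, horizon = 5) {
  structure(list(
    nagelkerke_r2 = nagelkerke_r2(fit),
    integrated_brier = as.numeric(integrated_brier_score(fit, cohort,
                                                         tau = horizon)),
    c_index = harrell_c_index(fit, cohort, horizon = horizon),
    discrimination_slope = discrimination_slope(fit, cohort, t = horizon),
    calibration_in_the_large = calibration_in_the_large(fit, cohort,
                                                        t = horizon),
    calibration_slope = calibration_slope(fit, cohort),
    horizon = horizon), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("Nagelkerke R2          %.4f\n",
                     "Integrated Brier       %.4f\n",
                     "C-index                %.4f\n",
                     "Discrimination slope   %.4f\n",
                     "Calibration in large   %.4f\n",
                     "Calibration slope      %.4f\n"),
              x$nagelkerke_r2, x$integrated_brier, x$c_index,
              x$discrimination_slope, x$calibration_in_the_large,
              x$calibration_slope))
  invisible(x)
}
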