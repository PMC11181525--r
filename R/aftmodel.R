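#' Normalize survey weights
#'
#' Pooled multi-cycle survey weights are divided by the number of cycles;
#' for likelihood-based inference they are additionally rescaled to mean
#' one (weighted point estimates are invariant to this rescaling, the
#' log-likelihood scales by the constant).
#'
#' @param weights strictly positive numeric vector.
#' @param n_cycles number of pooled survey cycles (default 1).
#' @param mean_one also rescale to mean 1 (default TRUE).
#' @return normalized weights, with attribute `mean_one` recording the
#'   rescale flag.
#' @export
normalize_weights <- function(weights, n_cycles = 1L, mean_one = TRUE) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stopf("weights must be strictly positive")
  w <- weights / n_cycles
  if (mean_one) w <- w / mean(w)
  attr(w, "mean_one") <- mean_one
  w
}

# Weighted survreg occasionally collapses (scale -> 0 or Inf) from its
# default initialization when nearly all mass sits at the horizon. The
# ladder: plain weighted fit; if degenerate, refit initialized from the
# (stable) unweighted fit; then up to 3 jittered restarts.
survreg_robust <- function(fml, dat, scale_arg, ctrl) {
  ok <- function(f) {
    !is.null(f) && !anyNA(stats::coef(f)) &&
      (scale_arg > 0 || (f$scale > 1e-4 && f$scale < 1e3))
  }
  run <- function(init = NULL) {
    tryCatch(suppressWarnings(
      survival::survreg(fml, data = dat, weights = .w, dist = "weibull",
                        scale = scale_arg, control = ctrl, init = init)),
      error = function(e) NULL)
  }
  f <- run()
  if (ok(f)) return(f)
  fu <- tryCatch(suppressWarnings(
    survival::survreg(fml, data = dat, dist = "weibull", scale = scale_arg,
                      control = ctrl)), error = function(e) NULL)
  if (!is.null(fu) && !anyNA(stats::coef(fu))) {
    init <- stats::coef(fu)
    if (scale_arg == 0) init <- c(init, log(max(fu$scale, 1e-3)))
    f <- run(init)
    if (ok(f)) return(f)
    old <- .Random.seed_guard()
    on.exit(old(), add = TRUE)
    for (k in 1:3) {
      set.seed(k)
      f <- run(init + stats::rnorm(length(init), 0, 0.05))
      if (ok(f)) return(f)
    }
  }
  if (is.null(f)) stopf("Weibull AFT fit failed to converge after restarts")
  f
}

#' Fit a survey-weighted Weibull accelerated failure time model
#'
#' Maximizes the weighted log-likelihood of the log-time location-scale
#' model `log T = mu + x beta + sigma W` with standard minimum
#' extreme-value `W`, i.e. `S(t|x) = exp(-exp((log t - mu - x beta)/sigma))`.
#' Censored rows contribute `log S`, events the log density. The null
#' (intercept + scale) model is fitted on the same rows and weights.
#' Backed by [survival::survreg()]; the covariance is the inverse observed
#' information on `(mu, beta, log sigma)`.
#'
#' @param cohort data frame with time, event, weight and predictor columns.
#' @param predictors character vector of predictor column names
#'   (factors are dummy-encoded against their reference level; numeric
#'   columns, e.g. age, enter linearly). Default: roster predictors plus
#'   age when the cohort carries a roster attribute.
#' @param time,event,weights column names (defaults `"time"`, `"event"`,
#'   `"weight"`).
#' @param n_cycles divisor applied to the weights before mean-one
#'   rescaling (default 1: the generator already pools by cycle count).
#' @param scale_fixed fix the scale parameter at this value instead of
#'   estimating it (e.g. `1` for the exponential submodel).
#' @param roster optional roster used to set factor reference levels
#'   (default: the cohort's `roster` attribute).
#' @return object of class `weibull_aft_fit` with elements `mu`, `beta`,
#'   `sigma`, `shape`, `vcov` (rows/cols `(Intercept)`, coefficients,
#'   `Log(scale)` unless the scale is fixed), `loglik_fitted`,
#'   `loglik_null`, `effective_n`, `n_events`, `encoding`, `terms`,
#'   `xlevels`.
#' @export
fit_weibull_aft <- function(cohort, predictors = NULL, time = "time",
                            event = "event", weights = "weight",
                            n_cycles = 1L, scale_fixed = NULL,
                            roster = NULL) {
  roster <- roster %||% attr(cohort, "roster")
  if (is.null(predictors)) {
    if (is.null(roster)) stopf("predictors must be given without a roster")
    predictors <- c("age", roster_names(roster))
  }
  if (any(cohort[[time]] <= 0)) stopf("follow-up times must be positive")
  if (sum(cohort[[event]]) < 1) stopf("no events: model unfittable")
  dat <- cohort[c(time, event, predictors)]
  for (v in predictors) {
    if (anyNA(dat[[v]])) stopf("predictor '%s' has missing values", v)
    if (!is.null(roster) && v %in% roster_names(roster) &&
        is.factor(dat[[v]]))
      dat[[v]] <- stats::relevel(dat[[v]], ref = roster_get(roster, v)$ref)
  }
  w <- normalize_weights(cohort[[weights]], n_cycles = n_cycles)
  dat$.w <- as.numeric(w)
  real_n <- sum(dat$.w)
  # Factor levels with subjects but zero events make the MLE diverge
  # (survreg returns NA or an arbitrary huge coefficient). Stabilize with
  # one epsilon-weighted pseudo-event per such level: the level's
  # coefficient becomes large-but-finite with an enormous SE, everything
  # else moves by O(epsilon).
  stabilized <- character(0)
  for (v in predictors) {
    if (!is.factor(dat[[v]])) next
    for (lv in levels(dat[[v]])) {
      rows <- which(dat[[v]] == lv)
      if (length(rows) > 0 && sum(dat[[event]][rows]) == 0) {
        pseudo <- dat[rows[1L], , drop = FALSE]
        pseudo[[event]] <- 1L
        pseudo$.w <- 1e-3
        dat <- rbind(dat, pseudo)
        stabilized <- c(stabilized, paste0(v, lv))
      }
    }
  }
  fml <- stats::reformulate(predictors,
                            response = sprintf("survival::Surv(%s, %s)",
                                               time, event))
  ctrl <- survival::survreg.control(maxiter = 100, rel.tolerance = 1e-10)
  scale_arg <- if (is.null(scale_fixed)) 0 else scale_fixed
  fit <- survreg_robust(fml, dat, scale_arg, ctrl)
  fit0 <- survreg_robust(stats::reformulate("1",
                           response = sprintf("survival::Surv(%s, %s)",
                                              time, event)),
                         dat, scale_arg, ctrl)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("inestimable coefficients (%s): too few events or empty level",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  V <- stats::vcov(fit)
  if (anyNA(V)) stopf("singular information matrix: check for separation")
  enc <- lapply(fit$xlevels, function(l) l)
  out <- list(mu = unname(cf[1L]), beta = cf[-1L], sigma = fit$scale,
              shape = 1 / fit$scale, vcov = V,
              loglik_fitted = fit$loglik[2L], loglik_null = fit0$loglik[2L],
              effective_n = real_n, n = nrow(cohort),
              n_events = sum(dat$.w * dat[[event]]),
              stabilized_levels = stabilized,
              scale_fixed = scale_fixed,
              encoding = enc, terms = stats::delete.response(stats::terms(fit)),
              xlevels = fit$xlevels, predictors = predictors,
              time = time, event = event)
  class(out) <- "weibull_aft_fit"
  out
}

#' @export
print.weibull_aft_fit <- function(x, ...) {
  cat(sprintf("<weibull_aft_fit> %d predictors, sigma=%.4f, shape=%.4f\n",
              length(x$predictors), x$sigma, x$shape))
  cat(sprintf("  loglik %.2f (null %.2f), effective n %.1f\n",
              x$loglik_fitted, x$loglik_null, x$effective_n))
  invisible(x)
}

# Parameter vector (mu, beta, log sigma) and matching covariance.
fit_theta <- function(fit) {
  th <- c(`(Intercept)` = fit$mu, fit$beta)
  if (is.null(fit$scale_fixed)) th <- c(th, `Log(scale)` = log(fit$sigma))
  th
}

#' Hazard ratios from a Weibull AFT fit
#'
#' In the Weibull AFT parametrization the hazard ratio of a level is
#' `exp(-beta / sigma)`; confidence intervals come from the delta method
#' on `g(beta, log sigma) = -beta / sigma` using the joint covariance.
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `term`, `hr`, `lo`, `hi`, `log_hr`,
#'   `se_log_hr`.
#' @export
hazard_ratios <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  sig <- fit$sigma
  terms <- names(fit$beta)
  V <- fit$vcov
  has_ls <- is.null(fit$scale_fixed)
  res <- lapply(terms, function(tm) {
    b <- fit$beta[[tm]]
    g <- -b / sig
    if (has_ls) {
      idx <- c(tm, "Log(scale)")
      grad <- c(-1 / sig, b / sig)
      var_g <- drop(t(grad) %*% V[idx, idx] %*% grad)
    } else {
      var_g <- V[tm, tm] / sig^2
    }
    se <- sqrt(var_g)
    data.frame(term = tm, hr = exp(g), lo = exp(g - z * se),
               hi = exp(g + z * se), log_hr = g, se_log_hr = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Predicted event risk by time t
#'
#' `P(T <= t | x) = 1 - exp(-exp((log t - mu - x beta) / sigma))`.
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param newdata data frame with the fit's predictor columns.
#' @param t horizon in years (scalar or per-row vector).
#' @param cap_age if TRUE, use the subject-specific horizon
#'   `min(t, max_age - age)` (requires an `age` column).
#' @param max_age administrative age bound used when `cap_age = TRUE`.
#' @return numeric vector of event probabilities.
#' @export
predict_risk <- function(fit, newdata, t, cap_age = FALSE, max_age = 75) {
  lp <- predict_lp(fit, newdata)
  if (cap_age) t <- pmin(t, max_age - newdata$age)
  if (any(t <= 0)) stopf("prediction horizon must be positive")
  1 - exp(-exp((log(t) - lp) / fit$sigma))
}

# Linear predictor mu + x beta for new data.
predict_lp <- function(fit, newdata) {
  roster_vars <- names(fit$xlevels)
  for (v in roster_vars) {
    lev <- levels(newdata[[v]])
    if (!all(levels(droplevels(newdata[[v]])) %in% fit$xlevels[[v]]))
      stopf("unknown category level in '%s'", v)
    newdata[[v]] <- factor(as.character(newdata[[v]]),
                           levels = fit$xlevels[[v]])
  }
  mm <- stats::model.matrix(fit$terms, newdata, xlev = fit$xlevels)
  unname(drop(mm %*% c(fit$mu, fit$beta)))
}

#' Pool Weibull AFT fits across multiply-imputed datasets (Rubin's rules)
#'
#' Pools the parameter vector `(mu, beta, log sigma)`: pooled estimate =
#' mean; within-variance `W` = mean covariance; between-variance `B` =
#' sample covariance of the per-dataset estimates; total `T = W +
#' (1 + 1/m) B`; per-parameter small-sample degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2`.
#'
#' @param fits list of `weibull_aft_fit` objects with identical encodings.
#' @return object of class `pooled_estimates` with `qbar`, `W`, `B`,
#'   `T` (matrices), `df`, `m`.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  stopifnot(m >= 1)
  ths <- lapply(fits, fit_theta)
  nm <- names(ths[[1]])
  for (th in ths) if (!identical(names(th), nm))
    stopf("mismatched parameter encodings across fits")
  Q <- do.call(rbind, ths)
  qbar <- colMeans(Q)
  Vs <- lapply(fits, function(f) f$vcov[nm, nm, drop = FALSE])
  W <- Reduce(`+`, Vs) / m
  B <- if (m > 1) stats::cov(Q) else matrix(0, length(nm), length(nm),
                                            dimnames = list(nm, nm))
  Tm <- W + (1 + 1 / m) * B
  bd <- pmax(diag(B), 0)
  df <- ifelse(bd > 0,
               (m - 1) * (1 + diag(W) / ((1 + 1 / m) * bd))^2, Inf)
  structure(list(qbar = qbar, W = W, B = B, T = Tm,
                 df = stats::setNames(df, nm), m = m),
            class = "pooled_estimates")
}

#' Rubin-pooled hazard ratios
#'
#' Pools the per-dataset log hazard ratios `-beta/sigma` (delta-method
#' within-variance) across imputed datasets; CIs use the Student-t
#' reference with Rubin's degrees of freedom.
#'
#' @param fits list of `weibull_aft_fit` objects.
#' @param level confidence level (default 0.95).
#' @return data.frame like [hazard_ratios()] plus columns `df`, `B`, `W`.
#' @export
pooled_hazard_ratios <- function(fits, level = 0.95) {
  m <- length(fits)
  hrs <- lapply(fits, hazard_ratios, level = level)
  terms <- hrs[[1]]$term
  out <- lapply(seq_along(terms), function(j) {
    g <- vapply(hrs, function(h) h$log_hr[j], numeric(1))
    v <- vapply(hrs, function(h) h$se_log_hr[j]^2, numeric(1))
    qb <- mean(g); W <- mean(v)
    B <- if (m > 1) stats::var(g) else 0
    Tv <- W + (1 + 1 / m) * B
    df <- if (B > 0) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
    tq <- if (is.finite(df)) stats::qt(1 - (1 - level) / 2, df) else
      stats::qnorm(1 - (1 - level) / 2)
    data.frame(term = terms[j], hr = exp(qb), lo = exp(qb - tq * sqrt(Tv)),
               hi = exp(qb + tq * sqrt(Tv)), log_hr = qb,
               se_log_hr = sqrt(Tv), df = df, B = B, W = W,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
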