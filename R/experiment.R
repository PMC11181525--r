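#' Run the four-method missing-data comparison on one cohort
#'
#' Executes impute -> fit -> hazard ratios / Rubin pooling -> evaluate
#' for each requested method on the same punctured cohort, so method
#' differences are attributable solely to missing-data handling.
#' Multiple-imputation performance is reported per dataset with its
#' (min, max) range; MI hazard ratios are Rubin-pooled.
#'
#' @param cohort a punctured `cohort_table` (missingness already applied)
#'   for a single sex, carrying its roster attribute.
#' @param model_predictors predictors of the risk model (default: age
#'   plus all roster variables).
#' @param methods subset of
#'   `c("complete_case", "mode", "fcs_single", "fcs_multiple")`.
#' @param m number of multiply-imputed datasets (default 5).
#' @param n_burnin FCS burn-in cycles (default 5).
#' @param horizon evaluation horizon in years (default 5).
#' @param fallback_strata see [imputation_config()].
#' @param seed integer seed driving all imputation chains.
#' @return object of class `comparison_report`: per-method fits, hazard
#'   ratio tables, performance reports (with MI ranges), Weibull
#'   parameters, a baseline table, the missingness summary and a run
#'   manifest.
#' @export
run_comparison <- function(cohort, model_predictors = NULL,
                           methods = c("complete_case", "mode",
                                       "fcs_single", "fcs_multiple"),
                           m = 5L, n_burnin = 5L, horizon = 5,
                           fallback_strata = NULL, seed = 1L) {
  roster <- attr(cohort, "roster")
  if (is.null(roster)) stopf("cohort must carry a roster attribute")
  model_predictors <- model_predictors %||% c("age", roster_names(roster))
  roster_vars <- intersect(model_predictors, roster_names(roster))
  methods <- match.arg(methods, several.ok = TRUE)
  results <- list()
  for (method in methods) {
    cfg <- imputation_config(method, n_burnin = n_burnin, m = m,
                             fallback_strata = fallback_strata, seed = seed)
    imp <- tryCatch(
      impute_cohort(cohort, cfg, model_predictors = roster_vars),
      error = function(e) stopf("[%s/impute] %s", method, conditionMessage(e)))
    fits <- tryCatch(
      lapply(imp$datasets, fit_weibull_aft, predictors = model_predictors,
             roster = roster),
      error = function(e) stopf("[%s/fit] %s", method, conditionMessage(e)))
    hr <- tryCatch(
      if (length(fits) > 1L) pooled_hazard_ratios(fits) else
        hazard_ratios(fits[[1L]]),
      error = function(e) stopf("[%s/hr] %s", method, conditionMessage(e)))
    perf <- tryCatch(
      lapply(seq_along(fits), function(d)
        performance_report(fits[[d]], imp$datasets[[d]], horizon = horizon)),
      error = function(e) stopf("[%s/evaluate] %s", method,
                                conditionMessage(e)))
    pooled <- if (length(fits) > 1L) pool_rubin(fits) else NULL
    results[[method]] <- list(
      method = method,
      imputation = imp,
      fits = fits,
      weibull = data.frame(
        dataset = seq_along(fits),
        scale = vapply(fits, `[[`, numeric(1), "sigma"),
        shape = vapply(fits, `[[`, numeric(1), "shape"),
        intercept = vapply(fits, `[[`, numeric(1), "mu")),
      hazard_ratios = hr,
      pooled = pooled,
      performance = perf,
      performance_range = perf_range(perf))
  }
  baseline <- baseline_table(
    cohort,
    stats::setNames(lapply(results, function(r)
      lapply(r$imputation$datasets, identity)), names(results)),
    vars = roster_vars)
  structure(list(
    sex = as.character(cohort$sex[1L]),
    methods = results,
    baseline = baseline,
    missingness = summarize_missingness(cohort, vars = roster_vars),
    manifest = list(seed = seed, m = m, n_burnin = n_burnin,
                    horizon = horizon, n = nrow(cohort),
                    methods = methods,
                    package_version = as.character(
                      utils::packageVersion("aftmiss")))),
    class = "comparison_report")
}

# (min, max) range of each measure across per-dataset performance reports.
perf_range <- function(perfs) {
  keys <- c("nagelkerke_r2", "integrated_brier", "c_index",
            "discrimination_slope", "calibration_in_the_large",
            "calibration_slope")
  vals <- vapply(keys, function(k)
    range(vapply(perfs, `[[`, numeric(1), k)), numeric(2))
  data.frame(measure = keys, min = vals[1L, ], max = vals[2L, ],
             row.names = NULL)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> sex=%s, n=%d\n", x$sex, x$manifest$n))
  for (method in names(x$methods)) {
    r <- x$methods[[method]]
    pr <- r$performance_range
    cat(sprintf("  %-13s scale=%s  c-index=%s\n", method,
                paste(sprintf("%.4f", range(r$weibull$scale)), collapse = "-"),
                paste(sprintf("%.4f",
                              unlist(pr[pr$measure == "c_index", c("min", "max")])),
                      collapse = "-")))
  }
  invisible(x)
}

#' Weighted baseline characteristics table
#'
#' Per variable and category: survey-weighted percent (among observed
#' cells) for the original punctured cohort and for each method's
#' completed dataset(s); MI columns carry the (min, max) percent across
#' the m datasets. Unweighted totals can be rounded to the nearest
#' thousand (a disclosure-rule reporting flag, not statistics).
#'
#' @param original the punctured input cohort.
#' @param method_datasets named list: method -> list of completed
#'   data.frames (length m; 1 for single-dataset methods).
#' @param vars categorical variables to tabulate.
#' @param weights weight column name (default `"weight"`).
#' @param round_totals round unweighted totals to the nearest thousand
#'   (default FALSE).
#' @return list of class `baseline_table`: `table` (long data.frame),
#'   `totals` (per method).
#' @export
baseline_table <- function(original, method_datasets, vars,
                           weights = "weight", round_totals = FALSE) {
  pct <- function(d, v) {
    w <- d[[weights]]
    obs <- !is.na(d[[v]])
    tapply(w[obs], d[[v]][obs], sum, default = 0) / sum(w[obs]) * 100
  }
  rows <- list()
  for (v in vars) {
    lev <- levels(original[[v]])
    orig <- pct(original, v)
    miss_pct <- mean(is.na(original[[v]])) * 100
    for (lv in lev) {
      row <- data.frame(variable = v, category = lv,
                        original = unname(orig[lv]),
                        original_missing_pct = miss_pct,
                        stringsAsFactors = FALSE)
      for (method in names(method_datasets)) {
        ps <- vapply(method_datasets[[method]],
                     function(d) unname(pct(d, v)[lv]), numeric(1))
        row[[paste0(method, "_min")]] <- min(ps)
        row[[paste0(method, "_max")]] <- max(ps)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  totals <- vapply(method_datasets, function(ds) {
    n <- nrow(ds[[1L]])
    if (round_totals) round(n / 1000) * 1000 else n
  }, numeric(1))
  totals <- c(original = if (round_totals)
    round(nrow(original) / 1000) * 1000 else nrow(original), totals)
  structure(list(table = tab, totals = totals), class = "baseline_table")
}

#' Calibration summary stratified by a predictor
#'
#' Observed percent of events (weighted Kaplan-Meier) versus mean
#' predicted risk within each level of a fully observed stratification
#' variable.
#'
#' @param fit a [fit_weibull_aft()] result.
#' @param cohort evaluation cohort.
#' @param strat_var fully observed stratification column name.
#' @param t horizon (default 5).
#' @return data.frame with one row per stratum: `stratum`, `n`,
#'   `sum_weight`, `mean_predicted`, `observed`, `n_events`,
#'   `no_events` flag.
#' @export
stratified_calibration <- function(fit, cohort, strat_var, t = 5) {
  if (anyNA(cohort[[strat_var]]))
    stopf("stratification variable '%s' must be fully observed", strat_var)
  risk <- predict_risk(fit, cohort, t)
  w <- as.numeric(normalize_weights(cohort$weight))
  sid <- factor(cohort[[strat_var]])
  out <- do.call(rbind, lapply(levels(sid), function(s) {
    sel <- sid == s
    nev <- sum(cohort[[fit$event]][sel])
    data.frame(stratum = s, n = sum(sel), sum_weight = sum(w[sel]),
               mean_predicted = stats::weighted.mean(risk[sel], w[sel]),
               observed = 1 - km_estimate(cohort[[fit$time]][sel],
                                          cohort[[fit$event]][sel],
                                          w[sel], t),
               n_events = nev, no_events = nev == 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
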