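#' Imputation configuration
#'
#' @param method one of `"complete_case"`, `"mode"`, `"fcs_single"`,
#'   `"fcs_multiple"`.
#' @param strata stratification keys for stratified imputation (default
#'   `c("sex", "cycle")`: every conditional model and every mode is
#'   computed within a sex-stratified survey cycle).
#' @param fallback_strata optional named list: variable -> named list
#'   mapping a stratum label (as produced by `interaction(..., sep=".")`)
#'   to the character vector of replacement stratum labels used when the
#'   variable has no observed values in that stratum (generalizes the
#'   "impute cycle 1 from the next two cycles" rule).
#' @param low_prevalence_threshold binary condition variables with a
#'   missing proportion below this threshold are deterministically filled
#'   with the absent level before FCS (default 0.01).
#' @param n_burnin number of full FCS cycles before a dataset is emitted
#'   (default 5).
#' @param m number of imputed datasets (forced to 1 for `fcs_single`;
#'   default 5 for `fcs_multiple`).
#' @param visit_order `"increasing_missingness"` (default; stabilizes the
#'   early conditionals) or `"roster_order"`.
#' @param include_outcome include the outcome representation (event
#'   indicator and log follow-up time) in every conditional model
#'   (default TRUE).
#' @param use_weights use survey weights inside conditional imputation
#'   models (default FALSE).
#' @param perturb draw conditional-model parameters from their approximate
#'   posterior before each imputation draw (proper imputation; default TRUE).
#' @param instrument record, per (variable, stratum) fit, which strata
#'   contributed fitting rows (leakage audit; default FALSE).
#' @param seed integer seed; chain d uses seed + d.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(method = c("complete_case", "mode",
                                         "fcs_single", "fcs_multiple"),
                              strata = c("sex", "cycle"),
                              fallback_strata = NULL,
                              low_prevalence_threshold = 0.01,
                              n_burnin = 5L, m = NULL,
                              visit_order = c("increasing_missingness",
                                              "roster_order"),
                              include_outcome = TRUE, use_weights = FALSE,
                              perturb = TRUE, instrument = FALSE, seed = 1L) {
  method <- match.arg(method)
  visit_order <- match.arg(visit_order)
  m <- as.integer(m %||% if (method == "fcs_multiple") 5L else 1L)
  if (method != "fcs_multiple") m <- 1L
  stopifnot(m >= 1L, n_burnin >= 1L,
            low_prevalence_threshold >= 0, low_prevalence_threshold < 1)
  structure(list(method = method, strata = strata,
                 fallback_strata = fallback_strata,
                 low_prevalence_threshold = low_prevalence_threshold,
                 n_burnin = as.integer(n_burnin), m = m,
                 visit_order = visit_order,
                 include_outcome = include_outcome,
                 use_weights = use_weights, perturb = perturb,
                 instrument = instrument, seed = as.integer(seed)),
            class = "imputation_config")
}

imputed_set <- function(datasets, method, provenance, engines = NULL,
                        fit_log = NULL) {
  structure(list(datasets = datasets, method = method,
                 provenance = provenance, engines = engines,
                 fit_log = fit_log),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("<imputed_set> method=%s, m=%d dataset(s), %d imputed cell(s)\n",
              x$method, length(x$datasets),
              if (length(x$provenance)) sum(x$provenance[[1]]) else 0L))
  invisible(x)
}

stratum_id <- function(cohort, strata) {
  interaction(cohort[strata], drop = FALSE, sep = ".", lex.order = TRUE)
}

#' Complete-case analysis
#'
#' Retains exactly the rows with no missing cell among the model
#' predictors; weights, follow-up time and event indicator are untouched.
#'
#' @param cohort a `cohort_table`, possibly with missing cells.
#' @param model_predictors character vector of predictor columns.
#' @return an `imputed_set` with a single dataset.
#' @export
complete_case <- function(cohort, model_predictors) {
  miss <- vapply(model_predictors, function(v) is.na(cohort[[v]]),
                 logical(nrow(cohort)))
  keep <- !apply(matrix(miss, nrow = nrow(cohort)), 1L, any)
  if (!any(keep)) stopf("complete case removed every row: model unfittable")
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  prov <- matrix(FALSE, nrow(out), length(model_predictors),
                 dimnames = list(NULL, model_predictors))
  imputed_set(list(out), "complete_case", list(prov))
}

# Modal category of a variable within each stratum, with optional
# fallback strata for (variable, stratum) pairs with no observed value.
stratum_modes <- function(x, sid, levels, var, fallback_strata) {
  modes <- vapply(levels(sid), function(s) {
    m <- mode_category(x[sid == s], levels)
    if (!is.na(m)) return(m)
    fb <- fallback_strata[[var]][[s]]
    if (is.null(fb)) return(NA_character_)
    mode_category(x[sid %in% fb], levels)
  }, character(1))
  if (anyNA(modes)) {
    bad <- names(modes)[is.na(modes)]
    stopf("variable '%s': no observed values in stratum %s and no fallback",
          var, paste(bad, collapse = ", "))
  }
  modes
}

#' Stratified mode imputation
#'
#' Replaces every missing cell by the unweighted modal category of its
#' variable within its stratum (default: sex-stratified cycle). Ties are
#' broken deterministically by roster level order.
#'
#' @inheritParams complete_case
#' @param strata stratification keys (default `c("sex", "cycle")`).
#' @param vars variables to impute (default: all columns with missing
#'   cells among the roster predictors).
#' @param fallback_strata see [imputation_config()].
#' @return an `imputed_set` with a single dataset.
#' @export
mode_impute <- function(cohort, strata = c("sex", "cycle"), vars = NULL,
                        fallback_strata = NULL) {
  if (is.null(vars)) vars <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  sid <- stratum_id(cohort, strata)
  out <- cohort
  prov <- matrix(FALSE, nrow(cohort), length(vars),
                 dimnames = list(NULL, vars))
  for (v in vars) {
    x <- out[[v]]
    lev <- levels(x) %||% sort(unique(stats::na.omit(as.character(x))))
    modes <- stratum_modes(as.character(x), sid, lev, v, fallback_strata)
    mis <- is.na(x)
    if (!any(mis)) next
    x[mis] <- factor(modes[as.character(sid[mis])], levels = lev)
    out[[v]] <- x
    prov[mis, v] <- TRUE
  }
  imputed_set(list(out), "mode", list(prov))
}

#' Deterministic fill of low-prevalence condition indicators
#'
#' Binary chronic-condition variables with a missing proportion strictly
#' below `threshold` have their missing cells set to the absent level
#' (the first roster level) before FCS begins — a convergence safeguard
#' for rare conditions.
#'
#' @inheritParams complete_case
#' @param threshold missing-proportion threshold (default 0.01).
#' @param roster predictor roster (default: the cohort's `roster`
#'   attribute).
#' @return list with `cohort` (filled copy) and `filled` (character
#'   vector of variables filled).
#' @export
low_prevalence_fill <- function(cohort, threshold = 0.01, roster = NULL) {
  roster <- roster %||% attr(cohort, "roster")
  filled <- character(0)
  for (entry in roster) {
    if (!isTRUE(entry$condition) || entry$type != "binary") next
    x <- cohort[[entry$name]]
    pm <- mean(is.na(x))
    if (pm > 0 && pm < threshold) {
      x[is.na(x)] <- entry$levels[1L]
      cohort[[entry$name]] <- x
      filled <- c(filled, entry$name)
    }
  }
  list(cohort = cohort, filled = filled)
}

#' Outcome representation for imputation models
#'
#' The survival outcome enters every conditional imputation model as two
#' covariates: the event indicator and the log follow-up time.
#'
#' @param cohort a `cohort_table` with positive `time`.
#' @return data.frame with columns `event` and `log_time`.
#' @export
outcome_representation <- function(cohort) {
  if (any(cohort$time <= 0)) stopf("follow-up times must be positive")
  data.frame(event = cohort$event, log_time = log(cohort$time))
}

#' Fully conditional specification imputation
#'
#' Within each stratum independently: initialize missing cells with the
#' stratum mode, then cycle `n_burnin` times over the incomplete
#' variables in visit order, at each step refitting the variable's
#' conditional model (on the rows where it was originally observed,
#' using the current completed values of all other roster variables,
#' age, and the outcome representation) and redrawing the originally
#' missing cells from the fitted predictive distribution with parameter
#' perturbation. After burn-in the current completed table is emitted;
#' chain `d` (d = 1..m) runs with seed `seed + d`.
#'
#' @inheritParams complete_case
#' @param config an [imputation_config()] with method `"fcs_single"` or
#'   `"fcs_multiple"`.
#' @param roster predictor roster (default: the cohort's attribute).
#' @return an `imputed_set` with `m` datasets.
#' @export
fcs_impute <- function(cohort, config, roster = NULL) {
  roster <- roster %||% attr(cohort, "roster")
  if (is.null(roster)) stopf("fcs_impute needs a predictor roster")
  rn <- roster_names(roster)
  incomplete <- rn[vapply(rn, function(v) anyNA(cohort[[v]]), logical(1))]
  n <- nrow(cohort)
  prov <- vapply(rn, function(v) is.na(cohort[[v]]), logical(n))
  prov <- matrix(prov, nrow = n, dimnames = list(NULL, rn))
  if (length(incomplete) == 0L) {
    return(imputed_set(rep(list(cohort), config$m), config$method,
                       rep(list(prov), config$m)))
  }
  sid <- stratum_id(cohort, config$strata)
  outrep <- if (config$include_outcome) outcome_representation(cohort) else NULL
  engines <- stats::setNames(vector("list", length(incomplete)), incomplete)
  fit_log <- list()
  old <- .Random.seed_guard()
  on.exit(old(), add = TRUE)

  run_chain <- function(d) {
    set.seed(derive_seed(config$seed + d, 404L))
    starts <- new.env(parent = emptyenv())   # warm starts across iterations
    cur <- cohort
    # initialize by stratum mode (with fallback)
    for (v in incomplete) {
      x <- as.character(cur[[v]])
      lev <- roster_get(roster, v)$levels
      modes <- stratum_modes(x, sid, lev, v, config$fallback_strata)
      mis <- is.na(x)
      x[mis] <- modes[as.character(sid[mis])]
      cur[[v]] <- factor(x, levels = lev)
    }
    for (s in levels(sid)) {
      rows <- which(sid == s)
      if (length(rows) == 0L) next
      mis_counts <- vapply(incomplete, function(v) sum(prov[rows, v]),
                           integer(1))
      active <- incomplete[mis_counts > 0L]
      if (length(active) == 0L) next
      if (config$visit_order == "increasing_missingness")
        active <- active[order(mis_counts[match(active, incomplete)])]
      for (iter in seq_len(config$n_burnin)) {
        for (v in active) {
          entry <- roster_get(roster, v)
          obs_all <- which(!prov[, v])
          obs <- intersect(rows, obs_all)
          strata_used <- s
          if (length(obs) == 0L) {
            fb <- config$fallback_strata[[v]][[s]]
            if (is.null(fb))
              stopf("variable '%s' unobserved in stratum %s, no fallback", v, s)
            obs <- intersect(which(sid %in% fb), obs_all)
            strata_used <- fb
          }
          mis <- intersect(rows, which(prov[, v]))
          use <- c(obs, mis)
          df_X <- cur[use, setdiff(rn, v), drop = FALSE]
          df_X$age <- cur$age[use]
          if (!is.null(outrep)) df_X <- cbind(df_X, outrep[use, , drop = FALSE])
          X <- stats::model.matrix(~ ., df_X)
          io <- seq_along(obs)
          im <- length(obs) + seq_along(mis)
          w <- if (config$use_weights) cur$weight[use] else NULL
          key <- paste(s, v, sep = "\r")
          sampler <- conditional_sampler(entry, cur[[v]][use], X, io, im,
                                         w = w, perturb = config$perturb,
                                         start = starts[[key]])
          starts[[key]] <- attr(sampler, "params")
          cur[[v]][mis] <- factor(sampler(), levels = entry$levels)
          if (iter == config$n_burnin) {
            engines[[v]] <<- unique(c(engines[[v]], attr(sampler, "engine")))
            if (config$instrument)
              fit_log[[length(fit_log) + 1L]] <<- data.frame(
                chain = d, variable = v, stratum = s,
                strata_used = paste(strata_used, collapse = "+"),
                engine = attr(sampler, "engine"),
                n_obs = length(obs), n_mis = length(mis))
          }
        }
      }
    }
    cur
  }
  datasets <- lapply(seq_len(config$m), run_chain)
  imputed_set(datasets, config$method, rep(list(prov), config$m),
              engines = engines,
              fit_log = if (length(fit_log)) do.call(rbind, fit_log) else NULL)
}

#' Impute a cohort under one of the four strategies
#'
#' Dispatcher for the four missing-data strategies: complete case,
#' stratified mode, FCS single imputation (m = 1), FCS multiple
#' imputation (m = 5 by default). FCS methods apply
#' [low_prevalence_fill()] first.
#'
#' @inheritParams complete_case
#' @param config an [imputation_config()].
#' @param model_predictors predictors defining complete-case eligibility
#'   (default: all roster variables).
#' @param roster predictor roster (default: the cohort's attribute).
#' @return an `imputed_set`.
#' @export
impute_cohort <- function(cohort, config, model_predictors = NULL,
                          roster = NULL) {
  roster <- roster %||% attr(cohort, "roster")
  model_predictors <- model_predictors %||% roster_names(roster)
  switch(config$method,
    complete_case = complete_case(cohort, model_predictors),
    mode = mode_impute(cohort, strata = config$strata,
                       vars = roster_names(roster)[
                         vapply(roster_names(roster),
                                function(v) anyNA(cohort[[v]]), logical(1))],
                       fallback_strata = config$fallback_strata),
    fcs_single = ,
    fcs_multiple = {
      lp <- low_prevalence_fill(cohort, config$low_prevalence_threshold,
                                roster)
      out <- fcs_impute(lp$cohort, config, roster)
      # provenance must still flag the deterministic fills
      for (v in lp$filled) for (d in seq_along(out$provenance))
        out$provenance[[d]][, v] <- out$provenance[[d]][, v] |
          (is.na(cohort[[v]]))
      out$low_prevalence_filled <- lp$filled
      out
    })
}
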