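#' Generator configuration for a synthetic survey cohort
#'
#' Describes the complete outcome process of one sex-specific cohort:
#' predictor roster, age-band marginals, true Weibull accelerated failure
#' time (AFT) parameters, target 5-year event rate, administrative
#' censoring bounds and the survey-weight distribution. The log death
#' time is `mu + x beta + sigma W` with `W` standard minimum
#' extreme value, so `S(t|x) = exp(-exp((log t - mu - x beta)/sigma))`.
#'
#' @param sex cohort label (`"female"` or `"male"`, free-form allowed).
#' @param n number of subjects for this sex.
#' @param roster list of [roster_entry()] objects (defaults to the
#'   sex-matched default roster).
#' @param n_cycles number of pooled survey cycles (default 6); pooled
#'   weights are divided by this count.
#' @param age_bands data frame with columns `lower`, `upper`, `prob`
#'   (band marginals; age is uniform within its band).
#' @param beta_age true log-time coefficient per year of age (default
#'   `-sigma * log(1.08)`, i.e. hazard ratio 1.08/year).
#' @param sigma true AFT scale (default 0.82).
#' @param target_event_rate per-sex 5-year premature-death proportion in
#'   (0, 0.5); defaults 0.0141 (female) / 0.0206 (male).
#' @param horizon follow-up horizon in years (default 5).
#' @param max_age administrative age bound in years (default 75): follow-up
#'   stops at the 75th birthday.
#' @param copula_rho exchangeable latent Gaussian correlation among
#'   categorical predictors (default 0.2).
#' @param weight_meanlog,weight_sdlog log-normal survey-weight parameters
#'   (defaults 0 and 0.5) before division by `n_cycles`.
#' @param censor_rate optional exponential random-censoring rate (events
#'   per year); `NULL` (default) disables random censoring so that all
#'   censoring is administrative.
#' @param mu true AFT intercept (log-years); `NULL` (default) means
#'   "solve by [calibrate_intercept()] at generation time".
#' @param probe_n probe-sample size used by [calibrate_intercept()].
#' @param seed integer seed; every draw of the generator derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(sex = c("female", "male"), n = 20000,
                             roster = NULL, n_cycles = 6L,
                             age_bands = NULL, beta_age = NULL,
                             sigma = 0.82, target_event_rate = NULL,
                             horizon = 5, max_age = 75, copula_rho = 0.2,
                             weight_meanlog = 0, weight_sdlog = 0.5,
                             censor_rate = NULL, mu = NULL,
                             probe_n = 200000L, seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(roster))
    roster <- if (sex == "female") default_roster_female(sigma) else
      default_roster_male(sigma)
  if (is.null(target_event_rate))
    target_event_rate <- if (sex == "female") 0.0141 else 0.0206
  if (is.null(age_bands)) {
    probs <- if (sex == "female") c(12.7, 17.4, 20.6, 21.3, 17.0, 11.1) else
      c(13.6, 18.5, 20.9, 20.5, 16.8, 9.9)
    age_bands <- data.frame(lower = c(18, 25, 35, 45, 55, 65),
                            upper = c(25, 35, 45, 55, 65, 75),
                            prob = normalize_probs(probs))
  }
  if (is.null(beta_age)) beta_age <- -sigma * log(1.08)
  stopifnot(n >= 1, n_cycles >= 1, sigma > 0, horizon > 0,
            copula_rho >= 0, copula_rho < 1)
  if (abs(sum(age_bands$prob) - 1) > 1e-12)
    stopf("age band probabilities must sum to 1")
  if (target_event_rate <= 0 || target_event_rate >= 0.5)
    stopf("target_event_rate must lie in (0, 0.5)")
  structure(list(sex = sex, n = as.integer(n), roster = roster,
                 n_cycles = as.integer(n_cycles), age_bands = age_bands,
                 beta_age = beta_age, sigma = sigma,
                 target_event_rate = target_event_rate, horizon = horizon,
                 max_age = max_age, copula_rho = copula_rho,
                 weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
                 censor_rate = censor_rate, mu = mu,
                 probe_n = as.integer(probe_n), seed = as.integer(seed)),
            class = "generator_config")
}

# Draw ages and the copula-coupled categorical design for n subjects.
# Assumes the RNG state is already set by the caller.
draw_design <- function(config, n) {
  bands <- config$age_bands
  band <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$prob)
  age <- stats::runif(n, bands$lower[band], bands$upper[band])
  p <- length(config$roster)
  rho <- config$copula_rho
  z0 <- stats::rnorm(n)
  z <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(stats::rnorm(n * p), n, p)
  X <- vector("list", p)
  for (j in seq_len(p)) {
    entry <- config$roster[[j]]
    u <- stats::pnorm(z[, j])
    idx <- findInterval(u, cumsum(entry$probs), left.open = TRUE) + 1L
    idx[idx > length(entry$levels)] <- length(entry$levels)
    X[[j]] <- factor(entry$levels[idx], levels = entry$levels)
  }
  names(X) <- roster_names(config$roster)
  list(age = age, X = X)
}

# Linear predictor x beta (excluding the intercept) for a design.
design_lp <- function(config, age, X) {
  lp <- config$beta_age * age
  for (entry in config$roster)
    lp <- lp + entry$beta[as.integer(X[[entry$name]])]
  unname(lp)
}

#' Calibrate the generator intercept to the target event rate
#'
#' Solves for the AFT intercept `mu` such that the expected fraction of
#' subjects whose simulated death time falls at or before
#' `min(horizon, max_age - age)` equals `target_event_rate`. On a fixed
#' probe sample of `probe_n` subjects the condition "death by the bound"
#' is `mu <= log(bound_i) - x_i beta - sigma W_i`, so the calibrated
#' intercept is the empirical `(1 - rate)` quantile of those per-subject
#' thresholds (exact inversion of the probe root-finding problem).
#'
#' @param config a [generator_config()].
#' @return the intercept `mu` (log-years).
#' @export
calibrate_intercept <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_guard()
  on.exit(old(), add = TRUE)
  set.seed(derive_seed(config$seed, 101L))
  n <- config$probe_n
  des <- draw_design(config, n)
  lp <- design_lp(config, des$age, des$X)
  W <- log(stats::rexp(n))
  bound <- pmin(config$horizon, config$max_age - des$age)
  thr <- log(bound) - lp - config$sigma * W
  mu <- unname(stats::quantile(thr, 1 - config$target_event_rate, type = 1))
  if (!is.finite(mu))
    stopf("intercept calibration failed: infeasible configuration")
  achieved <- mean(thr >= mu)
  if (abs(achieved - config$target_event_rate) > 1e-3)
    stopf("intercept calibration off target (achieved %.4f)", achieved)
  mu
}

# Save/restore the global RNG state so generator calls are self-contained.
.Random.seed_guard <- function() {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
  }
}

#' Generate a complete synthetic cohort
#'
#' Draws one sex-specific cohort from the configured outcome process:
#' age from band marginals (uniform within band), categorical predictors
#' jointly through an exchangeable Gaussian copula cut at the marginal
#' quantiles, log death time `mu + x beta + sigma W` with standard
#' minimum-extreme-value `W`, administrative censoring at `horizon` years
#' or the `max_age`-th birthday (optional exponential random censoring),
#' and log-normal survey weights divided by the number of cycles.
#' Bit-for-bit reproducible from `(config, seed)`.
#'
#' @param config a [generator_config()].
#' @return A `data.frame` (class `cohort_table`) with columns `sex`,
#'   `cycle`, `age`, the roster predictors (factors), `weight`, `time`,
#'   `event`; attributes `roster` and `true_params` (`mu`, `sigma`,
#'   `beta_age`, per-level `beta`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n < 1L) stopf("n_per_sex must be >= 1")
  mu <- config$mu %||% calibrate_intercept(config)
  old <- .Random.seed_guard()
  on.exit(old(), add = TRUE)
  set.seed(derive_seed(config$seed, 202L))
  n <- config$n
  cycle <- sample.int(config$n_cycles, n, replace = TRUE)
  des <- draw_design(config, n)
  lp <- design_lp(config, des$age, des$X)
  W <- log(stats::rexp(n))
  death <- exp(mu + lp + config$sigma * W)
  bound <- pmin(config$horizon, config$max_age - des$age)
  if (!is.null(config$censor_rate)) {
    cens <- stats::rexp(n, rate = config$censor_rate)
  } else cens <- rep(Inf, n)
  time <- pmin(death, bound, cens)
  event <- as.integer(death <= pmin(bound, cens))
  weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog) /
    config$n_cycles
  out <- data.frame(sex = config$sex, cycle = cycle, age = des$age,
                    stringsAsFactors = FALSE)
  for (nm in names(des$X)) out[[nm]] <- des$X[[nm]]
  out$weight <- weight
  out$time <- time
  out$event <- event
  beta <- lapply(config$roster, `[[`, "beta")
  names(beta) <- roster_names(config$roster)
  attr(out, "roster") <- config$roster
  attr(out, "true_params") <- list(mu = mu, sigma = config$sigma,
                                   beta_age = config$beta_age, beta = beta)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Missingness specification
#'
#' One entry per variable to puncture. MCAR entries set each cell missing
#' independently with probability `rate`; MAR entries set cells missing
#' with probability `expit(alpha + drivers . mar_log_odds)` where `alpha`
#' is solved numerically so the marginal rate hits the target.
#'
#' @param ... entries built with [miss_entry()].
#' @param seed integer seed controlling the puncturing draws.
#' @return object of class `missingness_spec`.
#' @export
missingness_spec <- function(..., seed = 1L) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !inherits(entries[[1]], "miss_entry"))
    entries <- entries[[1]]
  for (e in entries) stopifnot(inherits(e, "miss_entry"))
  structure(list(entries = entries, seed = as.integer(seed)),
            class = "missingness_spec")
}

#' @rdname missingness_spec
#' @param var target variable name.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rate target marginal missing proportion in `[0, 1)`.
#' @param mar_log_odds named numeric vector of log-odds coefficients on
#'   fully observed numeric driver columns (e.g. `c(event = 1)`); required
#'   for MAR, must be empty for MCAR.
#' @export
miss_entry <- function(var, mechanism = c("MCAR", "MAR"), rate,
                       mar_log_odds = NULL) {
  mechanism <- match.arg(mechanism)
  if (rate < 0 || rate >= 1) stopf("'%s': rate must be in [0,1)", var)
  if (mechanism == "MCAR" && length(mar_log_odds) > 0)
    stopf("'%s': MCAR entries must have no drivers", var)
  if (mechanism == "MAR" &&
      (length(mar_log_odds) == 0 || is.null(names(mar_log_odds))))
    stopf("'%s': MAR entries need named driver coefficients", var)
  structure(list(var = var, mechanism = mechanism, rate = rate,
                 mar_log_odds = mar_log_odds), class = "miss_entry")
}

#' Default missingness scenario (MAR on the outcome)
#'
#' Per-variable target rates follow the observed missingness pattern of
#' the pooled survey cohort (income around 11%/8%, education 4.5%/6%,
#' BMI, smoking 1.5-3.5%, chronic conditions 0.1%). Variables above 1%
#' are MAR with a positive log-odds (+1) on the death indicator, so
#' decedents are more likely to have missing entries; the rest are MCAR.
#'
#' @param sex `"female"` or `"male"`.
#' @param seed integer seed.
#' @return a [missingness_spec()].
#' @export
default_missingness <- function(sex = c("female", "male"), seed = 1L) {
  sex <- match.arg(sex)
  ev <- c(event = 1.0)
  entries <- if (sex == "female") list(
    miss_entry("income", "MAR", 0.109, ev),
    miss_entry("education", "MAR", 0.045, ev),
    miss_entry("bmi", "MAR", 0.034, ev),
    miss_entry("smoking", "MAR", 0.031, ev),
    miss_entry("physact", "MCAR", 0.016),
    miss_entry("selfhealth", "MCAR", 0.001),
    miss_entry("copd", "MCAR", 0.001),
    miss_entry("heart_disease", "MCAR", 0.001),
    miss_entry("diabetes", "MCAR", 0.001),
    miss_entry("cancer", "MCAR", 0.001),
    miss_entry("stroke", "MCAR", 0.0005)
  ) else list(
    miss_entry("income", "MAR", 0.082, ev),
    miss_entry("education", "MAR", 0.060, ev),
    miss_entry("smoking", "MAR", 0.035, ev),
    miss_entry("marital", "MCAR", 0.001),
    miss_entry("selfhealth", "MCAR", 0.001),
    miss_entry("copd", "MCAR", 0.001),
    miss_entry("heart_disease", "MCAR", 0.001),
    miss_entry("diabetes", "MCAR", 0.001),
    miss_entry("cancer", "MCAR", 0.001),
    miss_entry("stroke", "MCAR", 0.0005),
    miss_entry("alzheimers", "MCAR", 0.001),
    miss_entry("arthritis", "MCAR", 0.001)
  )
  missingness_spec(entries, seed = seed)
}

#' Puncture a complete cohort with missing values
#'
#' @param cohort a complete `cohort_table` (no `NA` in targeted columns
#'   or MAR driver columns).
#' @param spec a [missingness_spec()].
#' @return list with `cohort` (punctured copy) and `mask` (logical matrix,
#'   one column per targeted variable, `TRUE` = cell set missing).
#' @export
apply_missingness <- function(cohort, spec) {
  stopifnot(inherits(spec, "missingness_spec"))
  n <- nrow(cohort)
  vars <- vapply(spec$entries, `[[`, character(1), "var")
  mask <- matrix(FALSE, n, length(vars), dimnames = list(NULL, vars))
  old <- .Random.seed_guard()
  on.exit(old(), add = TRUE)
  set.seed(derive_seed(spec$seed, 303L))
  for (e in spec$entries) {
    if (!e$var %in% names(cohort)) stopf("variable '%s' not in cohort", e$var)
    if (anyNA(cohort[[e$var]]))
      stopf("variable '%s' already has missing cells", e$var)
    if (e$rate == 0) next
    if (e$mechanism == "MCAR") {
      pmiss <- rep(e$rate, n)
    } else {
      drv <- names(e$mar_log_odds)
      for (d in drv) {
        if (!d %in% names(cohort)) stopf("MAR driver '%s' not in cohort", d)
        if (anyNA(cohort[[d]]) || d %in% vars)
          stopf("MAR driver '%s' must be never-missing under the spec", d)
        if (!is.numeric(cohort[[d]])) stopf("MAR driver '%s' must be numeric", d)
      }
      eta <- as.vector(as.matrix(cohort[drv]) %*% e$mar_log_odds)
      f <- function(a) mean(expit(a + eta)) - e$rate
      alpha <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
      pmiss <- expit(alpha + eta)
      if (abs(mean(pmiss) - e$rate) > 1e-3)
        stopf("MAR intercept calibration failed for '%s'", e$var)
    }
    hit <- stats::runif(n) < pmiss
    mask[, e$var] <- hit
    cohort[[e$var]][hit] <- NA
  }
  list(cohort = cohort, mask = mask)
}

#' Per-variable missing proportions by sex
#'
#' @param cohort a `cohort_table`, possibly punctured.
#' @param vars variables to summarize (default: all roster predictors).
#' @return data.frame with columns `sex`, `variable`, `n`, `n_missing`,
#'   `prop_missing` (unweighted).
#' @export
summarize_missingness <- function(cohort, vars = NULL) {
  if (is.null(vars)) {
    roster <- attr(cohort, "roster")
    vars <- if (!is.null(roster)) roster_names(roster) else
      setdiff(names(cohort), c("sex", "cycle", "age", "weight", "time", "event"))
  }
  out <- do.call(rbind, lapply(split(cohort, cohort$sex), function(d) {
    data.frame(sex = d$sex[1L], variable = vars, n = nrow(d),
               n_missing = vapply(vars, function(v) sum(is.na(d[[v]])), integer(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out$prop_missing <- out$n_missing / out$n
  rownames(out) <- NULL
  out
}
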