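# Shared fixtures. Expensive cohorts are cached so multiple test files can
# reuse the same generated data within one session.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(sex = "female", n = 20000, seed = 1, ...) {
  key <- paste(sex, n, seed, ..., sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- generator_config(sex, n = n, seed = seed, ...)
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

# Two-predictor roster for fast imputation tests.
tiny_roster <- function(sigma = 0.82) list(
  roster_entry("grade", c("low", "mid", "high"), c(0.3, 0.4, 0.3),
               hr_to_beta(c(low = 1.6, mid = 1.2), sigma), ref = "high",
               type = "ordinal"),
  roster_entry("flag", c("No", "Yes"), c(0.9, 0.1),
               hr_to_beta(c(Yes = 2.0), sigma),
               type = "binary", condition = TRUE)
)

tiny_config <- function(n = 4000, seed = 1, ...) {
  generator_config("female", n = n, roster = tiny_roster(), seed = seed, ...)
}

# Hand-built fit object for closed-form prediction/HR checks.
fake_fit <- function(mu, sigma, beta = NULL, vcov = NULL) {
  predictors <- names(beta) %||% character(0)
  fml <- if (length(predictors)) stats::reformulate(predictors) else ~1
  structure(list(mu = mu, beta = beta %||% stats::setNames(numeric(0),
                                                           character(0)),
                 sigma = sigma, shape = 1 / sigma, vcov = vcov,
                 scale_fixed = NULL, terms = stats::terms(fml),
                 xlevels = list(), predictors = predictors,
                 time = "time", event = "event"),
            class = "weibull_aft_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n = 20000 tiny-roster cohort for the MCAR marginal-matching property.
cached_cohort_tiny_mcar <- function() {
  key <- "tiny_mcar"
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(tiny_config(n = 20000, seed = 77))
  .cohort_cache[[key]]
}

roster_names_of <- function(cohort) {
  vapply(attr(cohort, "roster"), `[[`, character(1), "name")
}

# Random right-censored dataset with discrete (tie-prone) risks.
rand_censored_data <- function(n, seed) {
  set.seed(seed)
  time <- round(rexp(n, 0.3), 1) + 0.1
  event <- rbinom(n, 1, 0.6)
  risk <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)
  weight <- rlnorm(n, 0, 0.3)
  data.frame(time = time, event = event, risk = risk, weight = weight)
}

# Brute-force Harrell c-index: O(n^2) pair enumeration with half-ties.
brute_cindex <- function(time, event, risk) {
  conc <- 0; total <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      total <- total + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / total
}

# Brute-force Graf IPCW Brier score, independent double-loop version.
brute_ibs <- function(time, event, w, S, grid, tau) {
  n <- length(time)
  Gfit <- aftmiss:::km_fit(time, 1 - event, w)
  bs <- numeric(length(grid))
  for (g in seq_along(grid)) {
    tg <- grid[g]
    num <- 0
    Gg <- aftmiss:::km_eval(Gfit, tg)
    for (i in seq_len(n)) {
      if (time[i] <= tg && event[i] == 1) {
        Gi <- aftmiss:::km_eval(Gfit, time[i], left = TRUE)
        if (Gi > 0) num <- num + w[i] * S[i, g]^2 / Gi
      } else if (time[i] > tg) {
        if (Gg > 0) num <- num + w[i] * (1 - S[i, g])^2 / Gg
      }
    }
    bs[g] <- num / sum(w)
  }
  sum(diff(grid) * (head(bs, -1) + tail(bs, -1)) / 2) / tau
}
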