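make_small_cohort <- function() {
  roster <- tiny_roster()
  d <- data.frame(
    sex = "female",
    cycle = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    age = c(30, 40, 50, 60, 35, 45, 55, 65),
    grade = factor(c("low", "low", "mid", NA, "high", "high", "mid", NA),
                   levels = c("low", "mid", "high")),
    flag = factor(c("No", "No", "No", "Yes", "No", "No", "No", "No"),
                  levels = c("No", "Yes")),
    weight = 1, time = c(5, 5, 2, 5, 5, 1, 5, 5),
    event = c(0L, 0L, 1L, 0L, 0L, 1L, 0L, 0L))
  attr(d, "roster") <- roster
  class(d) <- c("cohort_table", "data.frame")
  d
}

test_that("complete_case keeps exactly the fully observed rows", {
  d <- make_small_cohort()
  cc <- complete_case(d, c("grade", "flag"))
  expect_equal(nrow(cc$datasets[[1]]), 6)
  expect_false(anyNA(cc$datasets[[1]]$grade))
  # complete cohort: identity
  d2 <- d[!is.na(d$grade), ]
  cc2 <- complete_case(d2, c("grade", "flag"))
  expect_equal(nrow(cc2$datasets[[1]]), nrow(d2))
  # all-missing: error
  d3 <- d; d3$grade[] <- NA
  expect_error(complete_case(d3, "grade"), "unfittable")
})

test_that("mode_impute fills with the stratum mode and roster-order ties", {
  d <- make_small_cohort()
  m <- mode_impute(d)
  # cycle 1 observed grades: low, low, mid -> mode low
  expect_equal(as.character(m$datasets[[1]]$grade[4]), "low")
  # cycle 2 observed grades: high, high, mid -> mode high
  expect_equal(as.character(m$datasets[[1]]$grade[8]), "high")
  expect_true(all(m$provenance[[1]][c(4, 8), "grade"]))
  # tie: equal counts -> first roster level
  dt <- d[1:4, ]
  dt$grade <- factor(c("mid", "low", NA, NA), levels = c("low", "mid", "high"))
  mt <- mode_impute(dt)
  expect_equal(as.character(mt$datasets[[1]]$grade[3:4]), c("low", "low"))
})

test_that("mode_impute agrees with a brute-force per-stratum tally", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    d <- data.frame(
      sex = "female", cycle = sample(1:3, n, TRUE),
      grade = factor(sample(c("low", "mid", "high", NA), n, TRUE,
                            prob = c(0.3, 0.3, 0.3, 0.1)),
                     levels = c("low", "mid", "high")))
    m <- mode_impute(d, vars = "grade")$datasets[[1]]
    for (cy in 1:3) {
      obs <- d$grade[d$cycle == cy]
      tab <- table(obs)
      expected <- names(tab)[which.max(tab)]   # which.max = first max
      filled <- m$grade[d$cycle == cy][is.na(d$grade[d$cycle == cy])]
      if (length(filled)) expect_true(all(as.character(filled) == expected))
    }
  }
})

test_that("low_prevalence_fill applies only below the threshold", {
  cfg <- tiny_config(n = 2000, seed = 5)
  co <- generate_cohort(cfg)
  sp <- missingness_spec(miss_entry("flag", "MCAR", 0.005),
                         miss_entry("grade", "MCAR", 0.02), seed = 2)
  punct <- apply_missingness(co, sp)$cohort
  lp <- low_prevalence_fill(punct, threshold = 0.01)
  expect_identical(lp$filled, "flag")
  expect_false(anyNA(lp$cohort$flag))
  expect_true(all(lp$cohort$flag[is.na(punct$flag)] == "No"))
  expect_true(anyNA(lp$cohort$grade))           # above threshold: untouched
  # threshold 0: nothing filled
  expect_length(low_prevalence_fill(punct, threshold = 0)$filled, 0)
})

test_that("outcome_representation returns the event and log time", {
  d <- data.frame(time = c(2.5, 5), event = c(1L, 0L))
  o <- outcome_representation(d)
  expect_equal(o$event, c(1L, 0L))
  expect_equal(o$log_time, log(c(2.5, 5)))
  expect_error(outcome_representation(data.frame(time = 0, event = 0)),
               "positive")
})

test_that("fcs_impute is the identity on a complete cohort", {
  co <- generate_cohort(tiny_config(n = 1000, seed = 7))
  imp <- fcs_impute(co, imputation_config("fcs_multiple", m = 3, seed = 1))
  expect_length(imp$datasets, 3)
  for (d in imp$datasets) expect_identical(d, co)
  expect_false(any(imp$provenance[[1]]))
})

test_that("fcs_impute completes data, preserves observed cells, m chains differ", {
  co <- generate_cohort(tiny_config(n = 6000, seed = 8))
  sp <- missingness_spec(miss_entry("grade", "MAR", 0.15, c(event = 1)),
                         miss_entry("flag", "MCAR", 0.05), seed = 4)
  punct <- apply_missingness(co, sp)$cohort
  imp <- impute_cohort(punct, imputation_config("fcs_multiple", m = 5,
                                                seed = 21))
  expect_length(imp$datasets, 5)
  obs_g <- !is.na(punct$grade)
  for (d in imp$datasets) {
    expect_false(anyNA(d$grade)); expect_false(anyNA(d$flag))
    expect_identical(d$grade[obs_g], punct$grade[obs_g])
    # stratum containment: only roster categories appear
    expect_true(all(d$grade %in% c("low", "mid", "high")))
  }
  pairs_differ <- vapply(2:5, function(k)
    !identical(imp$datasets[[1]]$grade, imp$datasets[[k]]$grade), logical(1))
  expect_true(all(pairs_differ))
  # determinism of the whole chain set
  imp2 <- impute_cohort(punct, imputation_config("fcs_multiple", m = 5,
                                                 seed = 21))
  expect_identical(imp$datasets, imp2$datasets)
})

test_that("FCS conditional models never leak across strata", {
  co <- generate_cohort(tiny_config(n = 3000, seed = 9))
  punct <- apply_missingness(
    co, missingness_spec(miss_entry("grade", "MCAR", 0.2), seed = 5))$cohort
  imp <- fcs_impute(punct, imputation_config("fcs_single", instrument = TRUE,
                                             seed = 2))
  expect_true(nrow(imp$fit_log) > 0)
  expect_true(all(imp$fit_log$strata_used == imp$fit_log$stratum))
})

test_that("imputed MCAR cells reproduce the observed category distribution", {
  # one incomplete ordinal variable, MCAR at 10%; the average chi-square
  # statistic of imputed vs observed marginals over 20 chains stays below
  # the alpha = 0.01 critical value
  co <- cached_cohort_tiny_mcar()
  stats <- vapply(1:20, function(s) {
    punct <- apply_missingness(
      co, missingness_spec(miss_entry("grade", "MCAR", 0.10), seed = s))$cohort
    imp <- fcs_impute(punct, imputation_config("fcs_single", seed = s))
    mis <- is.na(punct$grade)
    obs_p <- prop.table(table(punct$grade[!mis]))
    imp_tab <- table(imp$datasets[[1]]$grade[mis])
    suppressWarnings(chisq.test(imp_tab, p = obs_p)$statistic)
  }, numeric(1))
  expect_lt(mean(stats), qchisq(0.99, df = 2))
})

test_that("dropping the outcome from imputation models attenuates effects", {
  # MAR-on-outcome, 40% missing on one covariate: imputing without the
  # outcome representation pulls its fitted coefficient toward zero
  # (classic MAR attenuation); with the outcome it stays near truth.
  betas <- vapply(1:6, function(s) {
    co <- generate_cohort(tiny_config(n = 15000, seed = 100 + s))
    sp <- missingness_spec(miss_entry("grade", "MAR", 0.4, c(event = 1.5)),
                           seed = s)
    punct <- apply_missingness(co, sp)$cohort
    vapply(c(TRUE, FALSE), function(oc) {
      imp <- fcs_impute(punct, imputation_config("fcs_single",
                                                 include_outcome = oc,
                                                 seed = s))
      fit_weibull_aft(imp$datasets[[1]])$beta[["gradelow"]]
    }, numeric(1))
  }, numeric(2))
  # true gradelow coefficient: -0.82 * log(1.6) ~ -0.385
  expect_lt(mean(abs(betas[2, ])), mean(abs(betas[1, ])))
  expect_lt(abs(mean(betas[2, ])), abs(mean(betas[1, ])))
})

test_that("fallback strata rescue variables unobserved in a stratum", {
  d <- make_small_cohort()
  d$grade[d$cycle == 1] <- NA                  # cycle 1 fully unobserved
  fb <- list(grade = list("female.1" = "female.2"))
  m <- mode_impute(d, fallback_strata = fb)
  expect_equal(as.character(m$datasets[[1]]$grade[1:4]),
               rep("high", 4))                 # cycle 2 mode
  expect_error(mode_impute(d), "no fallback")
  imp <- fcs_impute(d, imputation_config("fcs_single", fallback_strata = fb,
                                         n_burnin = 2, seed = 1))
  expect_false(anyNA(imp$datasets[[1]]$grade))
})

test_that("impute_cohort dispatches and flags low-prevalence fills", {
  co <- generate_cohort(tiny_config(n = 4000, seed = 10))
  sp <- missingness_spec(miss_entry("grade", "MCAR", 0.1),
                         miss_entry("flag", "MCAR", 0.005), seed = 6)
  punct <- apply_missingness(co, sp)$cohort
  imp <- impute_cohort(punct, imputation_config("fcs_single", seed = 3))
  expect_identical(imp$low_prevalence_filled, "flag")
  expect_false(anyNA(imp$datasets[[1]]$flag))
  filled <- is.na(punct$flag)
  expect_true(all(imp$provenance[[1]][filled, "flag"]))
})
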