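test_that("km_estimate reproduces hand products and survfit", {
  expect_equal(km_estimate(c(2, 3, 4), c(0, 0, 0), t = 2.5), 1)
  expect_equal(km_estimate(c(1, 2, 3), c(1, 1, 1), t = 2.5), 1 / 3)
  # weighted oracle: survival::survfit on random small datasets
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:20, 1)
    time <- sample(1:8, n, TRUE) + runif(n) * 0.1
    event <- rbinom(n, 1, 0.6)
    w <- runif(n, 0.5, 2)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, weights = w)
    at <- sort(unique(time))
    mine <- km_estimate(time, event, w, at)
    theirs <- summary(sf, times = at)$surv
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("nagelkerke_r2 follows its formula and weight invariance", {
  f <- fake_fit(mu = 1, sigma = 1)
  f$loglik_fitted <- -500; f$loglik_null <- -500; f$effective_n <- 1000
  expect_equal(nagelkerke_r2(f), 0)
  f$loglik_fitted <- -450
  manual <- (1 - exp(-2 * 50 / 1000)) / (1 - exp(2 * -500 / 1000))
  expect_equal(nagelkerke_r2(f), manual, tolerance = 1e-12)
  # weight-rescale invariance via mean-one normalization inside the fit
  co <- generate_cohort(tiny_config(n = 3000, seed = 12))
  f1 <- fit_weibull_aft(co)
  co$weight <- co$weight * 7.3
  f2 <- fit_weibull_aft(co)
  expect_equal(nagelkerke_r2(f1), nagelkerke_r2(f2), tolerance = 1e-9)
})

test_that("Brier score closed forms hold on uncensored data", {
  n <- 50
  time <- rep(2, n); event <- rep(1, n); w <- rep(1, n)
  grid <- c(0, 1, 2, 3, 4)
  # perfect oracle: survival is the true step function of each subject
  S <- t(vapply(seq_len(n), function(i) as.numeric(grid < 2), numeric(5)))
  expect_equal(as.numeric(aftmiss:::ibs_core(time, event, w, S, grid, 4)), 0)
  # constant predicted risk 0.5 at all t: BS(t) = 0.25 everywhere
  S5 <- matrix(0.5, n, 5)
  time2 <- c(rep(1, 25), rep(10, 25)); event2 <- c(rep(1, 25), rep(0, 25))
  expect_equal(as.numeric(aftmiss:::ibs_core(time2, event2, w, S5, grid, 4)),
               0.25, tolerance = 1e-12)
})

test_that("IPCW Brier matches the brute-force double-loop oracle", {
  for (seed in 1:10) {
    d <- rand_censored_data(60, seed + 100)
    grid <- sort(unique(c(0, d$time[d$event == 1 & d$time <= 4], 4)))
    set.seed(seed)
    lp <- rnorm(60, 1, 0.5)
    S <- vapply(grid, function(tg)
      if (tg <= 0) rep(1, 60) else exp(-exp((log(tg) - lp) / 0.9)),
      numeric(60))
    mine <- aftmiss:::ibs_core(d$time, d$event, d$weight, S, grid, 4)
    oracle <- brute_ibs(d$time, d$event, d$weight, S, grid, 4)
    expect_equal(as.numeric(mine), oracle, tolerance = 1e-12)
  }
})

test_that("c-index handles perfect orderings, reversal and brute force", {
  time <- c(1, 2, 3); event <- c(1, 1, 1); risk <- c(0.9, 0.5, 0.1)
  expect_equal(aftmiss:::concordance_from_risk(time, event, risk), 1)
  c1 <- aftmiss:::concordance_from_risk
  for (seed in 1:10) {
    d <- rand_censored_data(80, seed)
    c_mine <- c1(d$time, d$event, d$risk)
    c_brute <- brute_cindex(d$time, d$event, d$risk)
    expect_equal(c_mine, c_brute, tolerance = 1e-12)
    # antisymmetry under risk reversal (ties stay at half weight)
    expect_equal(c1(d$time, d$event, -d$risk), 1 - c_mine, tolerance = 1e-12)
  }
  expect_error(c1(c(1, 1), c(0, 0), c(0.1, 0.2)), "comparable")
})

test_that("c-index is invariant to monotone transforms of risk", {
  d <- rand_censored_data(150, 55)
  c0 <- aftmiss:::concordance_from_risk(d$time, d$event, d$risk)
  expect_equal(aftmiss:::concordance_from_risk(d$time, d$event,
                                               qlogis(d$risk)), c0)
  expect_equal(aftmiss:::concordance_from_risk(d$time, d$event,
                                               d$risk^3), c0)
})

test_that("discrimination slope resolves status and weights correctly", {
  # all subjects share one risk -> 0; perfectly separated risks -> 1
  t5 <- c(1, 2, 5, 5, 0.5)
  ev <- c(1, 1, 0, 0, 0)       # last one censored before t: excluded
  w <- rep(1, 5)
  expect_equal(aftmiss:::ds_core(rep(0.3, 5), t5, ev, w, t = 5), 0)
  expect_equal(aftmiss:::ds_core(c(1, 1, 0, 0, 0.5), t5, ev, w, t = 5), 1)
  # 20-row worked fixture: difference of two weighted means
  set.seed(20)
  time <- c(runif(10, 0, 4.9), rep(5, 10))
  event <- c(rep(1, 10), rep(0, 10))
  risk <- runif(20); w20 <- runif(20, 0.5, 2)
  manual <- weighted.mean(risk[1:10], w20[1:10]) -
    weighted.mean(risk[11:20], w20[11:20])
  expect_equal(aftmiss:::ds_core(risk, time, event, w20, t = 5), manual,
               tolerance = 1e-15)
  expect_error(aftmiss:::ds_core(risk, rep(1, 20), rep(0, 20), w20, t = 5),
               "empty")
})

test_that("calibration-in-the-large matches manual KM minus mean risk", {
  co <- generate_cohort(tiny_config(n = 1000, seed = 13))
  f <- fit_weibull_aft(co)
  v <- calibration_in_the_large(f, co, t = 5)
  w <- as.numeric(normalize_weights(co$weight))
  manual <- (1 - km_estimate(co$time, co$event, w, 5)) -
    weighted.mean(predict_risk(f, co, 5), w)
  expect_equal(v, manual, tolerance = 1e-15)
  # shifting all predicted risks by +0.01 shifts the value by -0.01:
  # verified through the formula's linearity in the predicted term
  v_shift <- (1 - km_estimate(co$time, co$event, w, 5)) -
    weighted.mean(predict_risk(f, co, 5) + 0.01, w)
  expect_equal(v_shift, v - 0.01, tolerance = 1e-12)
})

test_that("calibration-in-the-large vanishes on large self-simulated data", {
  co <- cached_cohort("female", n = 50000, seed = 1)
  f <- fit_weibull_aft(co)
  expect_lt(abs(calibration_in_the_large(f, co, t = 5)), 0.002)
})

test_that("calibration slope is 1 on development data and 1/2 under doubled betas", {
  co <- generate_cohort(tiny_config(n = 5000, seed = 14))
  f <- fit_weibull_aft(co)
  expect_equal(calibration_slope(f, co), 1, tolerance = 1e-3)
  f2 <- f
  f2$beta <- f$beta * 2
  expect_equal(calibration_slope(f2, co), 0.5, tolerance = 0.02)
})

test_that("calibration slope is near 1 on an external validation sample", {
  # event-rich configuration (20% events, n = 1e5) so the Monte Carlo
  # spread of the slope is well inside the +-0.03 band
  cfg_dev <- generator_config("female", n = 100000, roster = tiny_roster(),
                              target_event_rate = 0.2, seed = 1)
  cfg_val <- generator_config("female", n = 100000, roster = tiny_roster(),
                              target_event_rate = 0.2, seed = 2)
  f <- fit_weibull_aft(generate_cohort(cfg_dev))
  expect_lt(abs(calibration_slope(f, generate_cohort(cfg_val)) - 1), 0.03)
})

test_that("calibration_curve partitions the cohort into monotone bins", {
  co <- generate_cohort(tiny_config(n = 4000, seed = 15))
  f <- fit_weibull_aft(co)
  cc <- calibration_curve(f, co, t = 5, n_bins = 10)
  expect_equal(sum(cc$n), nrow(co))
  expect_true(!is.unsorted(cc$mean_predicted))
  expect_true(all(cc$observed >= 0 & cc$observed <= 1))
})

test_that("all six measures are invariant to global weight rescaling", {
  co <- generate_cohort(tiny_config(n = 3000, seed = 16))
  f1 <- fit_weibull_aft(co)
  r1 <- performance_report(f1, co)
  co$weight <- co$weight * 12
  f2 <- fit_weibull_aft(co)
  r2 <- performance_report(f2, co)
  for (k in c("nagelkerke_r2", "integrated_brier", "c_index",
              "discrimination_slope", "calibration_in_the_large",
              "calibration_slope"))
    expect_equal(r1[[k]], r2[[k]], tolerance = 1e-8)
})

test_that("IBS grows along a constant-shift miscalibration family", {
  # start from the true generator parameters (the Brier optimum) so the
  # shift family is monotone rather than noise-dominated near zero
  co <- generate_cohort(tiny_config(n = 10000, seed = 18))
  f <- fit_weibull_aft(co)
  tp <- attr(co, "true_params")
  f$mu <- tp$mu; f$sigma <- tp$sigma; f$shape <- 1 / tp$sigma
  f$beta[["age"]] <- tp$beta_age
  f$beta[["gradelow"]] <- tp$beta$grade[["low"]]
  f$beta[["grademid"]] <- tp$beta$grade[["mid"]]
  f$beta[["flagYes"]] <- tp$beta$flag[["Yes"]]
  vals <- vapply(c(0, 0.5, 1, 1.5), function(s) {
    fs <- f; fs$mu <- f$mu - s     # uniformly inflates predicted risk
    as.numeric(integrated_brier_score(fs, co, tau = 5))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
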