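test_that("fold change follows its definition and flags from-zero rises", {
  expect_equal(fold_change(7e3, 1e3)$ratio, 7.0)
  expect_equal(fold_change(4.2e5, 4.2e5)$ratio, 1.0)
  fz <- fold_change(1.28e5, 0)
  expect_true(fz$from_zero)
  expect_equal(fz$final, 1.28e5)
  expect_true(is.na(fz$ratio))
  # scale invariance
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.1, 100)
    f <- runif(1, 1, 1e6); b <- runif(1, 1, 1e6)
    expect_equal(fold_change(a * f, a * b)$ratio, fold_change(f, b)$ratio,
                 tolerance = 1e-12)
  }
})

test_that("classification thresholds the terminal geometric-mean ratio", {
  pred <- closed_form_single(1e7, 500, 140, 0:20)
  cs_eq <- comparison_series(0:20, pred, pred)
  expect_equal(classify_engraftment(cs_eq)$classification, "TRACKING")
  expect_equal(classify_engraftment(cs_eq, factor = 1.01)$classification,
               "TRACKING")
  cs_hi <- comparison_series(0:20, 10 * pred, pred)
  expect_equal(classify_engraftment(cs_hi, factor = 2)$classification,
               "ABOVE_EXPECTED")
  cs_lo <- comparison_series(0:20, pred / 10, pred)
  expect_equal(classify_engraftment(cs_lo, factor = 2)$classification,
               "BELOW_EXPECTED")
  zero_pred <- comparison_series(1:6, rep(1, 6), rep(0, 6))
  expect_error(classify_engraftment(zero_pred), "undefined ratio")
  expect_error(classify_engraftment(cs_eq, factor = 1), "> 1")
})

test_that("classification is monotone in the measured values", {
  set.seed(31)
  pred <- closed_form_single(1e7, 500, 140, 0:19)
  rank_of <- c(BELOW_EXPECTED = 1, TRACKING = 2, ABOVE_EXPECTED = 3)
  for (i in 1:20) {
    meas <- pred * exp(rnorm(20, 0, 0.8))
    cl1 <- classify_engraftment(comparison_series(0:19, meas, pred))
    scale <- runif(1, 1, 20)
    cl2 <- classify_engraftment(comparison_series(0:19, scale * meas, pred))
    expect_gte(rank_of[cl2$classification], rank_of[cl1$classification])
  }
})

test_that("growth fitting is exact on noise-free model output", {
  ch <- default_chain(); sched <- default_schedule(); dose <- default_dose()
  for (g_true in c(1.0, 1.3)) {
    tr <- simulate_with_growth(ch, sched, dose, c(g_true, 1, 1), 31)
    fit <- fit_growth_multiplier(1:31,
                                 tr$concentrations["AC", as.character(1:31)],
                                 "AC", ch, sched, dose)
    expect_equal(fit$estimate, g_true, tolerance = 1e-6)
  }
  expect_error(
    fit_growth_multiplier(1:3, c(1, 2, 3), "AC", ch, sched, dose),
    "not estimable")
})

test_that("chain-order profile fitting recovers all compartments noise-free", {
  ch <- default_chain(); sched <- default_schedule(); dose <- default_dose()
  g_true <- c(AC = 1.2, TC = 0.9, DC = 0.95)
  tr <- simulate_with_growth(ch, sched, dose, g_true, 31)
  series <- lapply(ch$names, function(cp) {
    list(cycles = 1:31, measured = tr$concentrations[cp, as.character(1:31)])
  })
  names(series) <- ch$names
  fits <- fit_growth_profile(series, ch, sched, dose)
  for (cp in ch$names) {
    expect_equal(fits[[cp]]$estimate, unname(g_true[cp]), tolerance = 1e-5)
  }
})

test_that("noisy growth recovery lands near the generating multiplier", {
  ch <- default_chain(); sched <- default_schedule(); dose <- default_dose()
  tr <- simulate_with_growth(ch, sched, dose, c(1.2, 1, 1), 31)
  model <- tr$concentrations["AC", as.character(1:31)]
  set.seed(77)
  errs <- replicate(5, {
    meas <- model * exp(rnorm(31, 0, 0.1))
    fit_growth_multiplier(1:31, meas, "AC", ch, sched, dose)$estimate - 1.2
  })
  expect_lt(median(abs(errs)), 0.05)
})

test_that("bootstrap interval brackets the point estimate", {
  ch <- default_chain(); sched <- default_schedule(); dose <- default_dose()
  tr <- simulate_with_growth(ch, sched, dose, c(1.1, 1, 1), 25)
  set.seed(9)
  meas <- tr$concentrations["AC", as.character(1:25)] * exp(rnorm(25, 0, 0.1))
  fit <- fit_growth_multiplier(1:25, meas, "AC", ch, sched, dose, n_boot = 49)
  expect_length(fit$boot, 49)
  expect_lte(fit$ci[1], fit$estimate)
  expect_gte(fit$ci[2], fit$estimate)
  # seeded bootstrap is reproducible
  fit2 <- fit_growth_multiplier(1:25, meas, "AC", ch, sched, dose, n_boot = 49)
  expect_identical(fit$ci, fit2$ci)
})

test_that("engraftment report summarizes series and fits per bioreplicate", {
  cfg <- synth_config(seed = 3, bioreplicates = c("BR1", "BR2"),
                      qpcr_noise_sd = 0.05,
                      baseline_range = c(0, 0))
  qp <- gen_qpcr_trajectory(cfg)
  series <- lapply(qp, `[[`, "series")
  series <- lapply(series, function(s) { s$baseline <- 0; s })
  rep <- engraftment_report(series, reactor_chain(cfg$volumes),
                            feeding_schedule(cfg$transfer_volume),
                            dose_event(cfg$dose_compartment, cfg$dose_cells))
  expect_s3_class(rep, "engraftment_report")
  expect_equal(nrow(rep$summary), 6)
  # AC generated with net growth 1.2 classifies above expectation; the
  # downstream compartments are fed by the growing AC, so they also sit
  # above the no-growth prediction despite local net death
  ac <- rep$summary[rep$summary$compartment == "AC", ]
  expect_true(all(ac$classification == "ABOVE_EXPECTED"))
  expect_equal(rep$summary$fitted_growth_multiplier[
    rep$summary$bioreplicate == "BR1" & rep$summary$compartment == "AC"],
    1.2, tolerance = 0.05)
})
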