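test_that("mix implements the complete-mixing rule and its bounds", {
  expect_equal(mix(1, 0, 1, 2), 1.0)
  expect_equal(mix(140, 0, 500, 6.4e5), 5.0e5)
  for (c0 in c(0, 1, 3.7e5)) {
    expect_equal(mix(5, c0, 7, c0), c0)
  }
  set.seed(11)
  for (i in 1:50) {
    M1 <- runif(1, 0.1, 100); M2 <- runif(1, 0.1, 100)
    r1 <- runif(1, 0, 1e6); r2 <- runif(1, 0, 1e6)
    r <- mix(M1, r1, M2, r2)
    expect_gte(r, min(r1, r2))
    expect_lte(r, max(r1, r2))
  }
  expect_error(mix(0, 1, 0, 1), "degenerate")
  expect_error(mix(-1, 0, 5, 0), "non-negative")
})

test_that("closed-form single-compartment washout matches hand arithmetic", {
  expect_equal(closed_form_single(12345, 500, 140, 0), 12345)
  expect_equal(closed_form_single(1e6, 500, 140, 1), 7.8125e5)
  expect_equal(closed_form_single(1e6, 500, 140, 3), 4.76837158203125e5)
})

test_that("iterated single-compartment washout equals the closed form", {
  set.seed(42)
  for (i in 1:20) {
    V <- runif(1, 100, 1000)
    u <- runif(1, 10, 300)
    c0 <- 10^runif(1, 3, 9)
    n <- sample(1:100, 1)
    ch <- reactor_chain(c(X = V))
    tr <- predict_no_growth(ch, feeding_schedule(u), dose_event("X", c0 * V), n)
    expect_equal(tr$concentrations[1, n + 1], closed_form_single(c0, V, u, n),
                 tolerance = 1e-12)
  }
})

test_that("zero dose gives an all-zero trajectory and no waste", {
  tr <- predict_no_growth(default_chain(), default_schedule(),
                          dose_event("AC", 0), 20)
  expect_true(all(tr$concentrations == 0))
  expect_true(all(tr$cumulative_waste_cells == 0))
})

test_that("no-growth washout conserves dosed cells exactly", {
  set.seed(99)
  for (i in 1:10) {
    k <- sample(1:4, 1)
    vols <- setNames(runif(k, 100, 1000), paste0("C", seq_len(k)))
    ch <- reactor_chain(vols)
    sched <- feeding_schedule(runif(1, 10, 200))
    dose <- dose_event(sample(names(vols), 1), 10^runif(1, 6, 11))
    n <- sample(50:200, 1)
    tr <- predict_no_growth(ch, sched, dose, n)
    total <- system_cells(tr) + tr$cumulative_waste_cells + tr$clamped_cells
    expect_lt(max(abs(total - dose$total_cells)) / dose$total_cells, 1e-9)
    expect_true(all(diff(tr$cumulative_waste_cells) >= 0))
  }
})

test_that("dosed compartment decays monotonically and peaks order downstream", {
  tr <- predict_no_growth(default_chain(), default_schedule(),
                          default_dose(), 40)
  ac <- tr$concentrations["AC", ]
  expect_true(all(diff(ac) < 0))
  peaks <- apply(tr$concentrations, 1, which.max)
  expect_gt(peaks["TC"], 1)        # interior maximum downstream
  expect_gte(peaks["DC"], peaks["TC"])
  # every compartment washes toward zero
  tr_long <- predict_no_growth(default_chain(), default_schedule(),
                               default_dose(), 500)
  expect_lt(max(tr_long$concentrations[, 501]) /
            tr_long$concentrations["AC", 1], 1e-20)
})

test_that("growth simulation reduces to the no-growth model at g = 1", {
  set.seed(123)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    vols <- setNames(runif(k, 100, 1000), paste0("C", seq_len(k)))
    ch <- reactor_chain(vols)
    sched <- feeding_schedule(runif(1, 10, 200))
    dose <- dose_event("C1", 10^runif(1, 6, 10))
    n <- sample(10:60, 1)
    a <- predict_no_growth(ch, sched, dose, n)
    b <- simulate_with_growth(ch, sched, dose, rep(1, k), n)
    expect_identical(a$concentrations, b$concentrations)
    expect_identical(a$cumulative_waste_cells, b$cumulative_waste_cells)
  }
})

test_that("growth mechanics follow the per-cycle multiplier", {
  ch <- reactor_chain(c(X = 500))
  sched <- feeding_schedule(140)
  # growth exactly cancelling dilution holds the concentration constant
  g_bal <- (500 + 140) / 500
  tr <- simulate_with_growth(ch, sched, dose_event("X", 1e6 * 500), g_bal, 10)
  expect_equal(unname(tr$concentrations[1, ]), rep(1e6, 11), tolerance = 1e-12)
  # hand-iterated recurrence for g = 1.2, two cycles
  tr2 <- simulate_with_growth(ch, sched, dose_event("X", 1e6 * 500), 1.2, 2)
  expect_equal(tr2$concentrations[1, 3], 1e6 * (1.2 * 500 / 640)^2,
               tolerance = 1e-12)
  expect_error(simulate_with_growth(ch, sched, dose_event("X", 1), -0.5, 5),
               ">= 0")
})

test_that("model input validation catches bad chains and doses", {
  expect_error(reactor_chain(c(500, 600)), "names")
  expect_error(reactor_chain(c(AC = -5)), "> 0")
  expect_error(predict_no_growth(default_chain(), default_schedule(),
                                 dose_event("SIGMOID", 1e6), 10),
               "unknown dose compartment")
  expect_error(predict_no_growth(default_chain(), default_schedule(),
                                 dose_event("AC", 1e6, cycle = 20), 10),
               "exceeds n_cycles")
})

test_that("trajectory converts to a tidy long data frame", {
  tr <- predict_no_growth(default_chain(), default_schedule(),
                          default_dose(), 5)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 3 * 6)
  expect_named(df, c("cycle", "compartment", "concentration_cells_per_ml",
                     "cumulative_waste_cells"))
  expect_equal(df$concentration_cells_per_ml[df$cycle == 0 &
                                             df$compartment == "AC"],
               2.5e10 / 500)
})
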