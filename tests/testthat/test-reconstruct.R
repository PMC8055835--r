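km_stepfun <- function(steps) stats::stepfun(steps$time, c(1, steps$survival))

# max |S_reconstructed - S_input| over the input coordinate times
roundtrip_gap <- function(data, arm, endpoint, grid, risk_by = 3) {
  dig <- digitize_km(data, grid = grid,
                     risk_times = unique(c(seq(0, max(grid), by = risk_by),
                                           max(grid))),
                     endpoints = endpoint)
  co <- dig$km_points[dig$km_points$arm == arm, c("time", "survival")]
  rt <- dig$risk_table[dig$risk_table$arm == arm, c("time", "n_risk")]
  rec <- reconstruct_ipd(co, rt)
  km <- kaplan_meier(rec)
  max(abs(km_stepfun(km$steps)(co$time) - co$survival))
}

test_that("reconstruction is exact when there is no censoring", {
  d <- generate_ipd(exp_arm(120, rate = 0.1, name = "A"),
                    lifetable = NULL, seed = 5)
  gap <- roundtrip_gap(d, "A", "OS", grid = seq(0.5, 40, 0.5), risk_by = 5)
  expect_lt(gap, 1e-9)
})

test_that("reconstruction reproduces censored curves within 0.02", {
  cal <- default_calibration(c(200L, 200L))
  d <- generate_ipd(cal$arms, cal$lifetable, seed = 6)
  for (a in c("A+C", "C")) {
    gap <- roundtrip_gap(d, a, "OS", grid = seq(0.25, 24, 0.25))
    expect_lt(gap, 0.02)
  }
})

test_that("round-trip accuracy holds across seeds at moderate censoring", {
  # ~20% censoring from the administrative cutoff
  for (seed in 1:20) {
    sp <- arm_spec("A", 150, 0, "weibull", c(shape = 1.3, scale = 14),
                   "lognormal", c(meanlog = 1.5, sdlog = 0.7),
                   accrual_months = 8, admin_censor_months = 26,
                   dropout_rate = 0.004)
    d <- generate_ipd(sp, lifetable = NULL, seed = seed)
    cens <- 1 - mean(d$os_event)
    expect_lt(cens, 0.30)
    gap <- roundtrip_gap(d, "A", "OS", grid = seq(0.25, 26, 0.25))
    expect_lt(gap, 0.02)
  }
})

test_that("flat segments with dropping risk counts become censorings", {
  # survival flat on (1, 10] while n_risk falls: only censorings there
  co <- data.frame(time = c(1, 5, 10), survival = c(0.9, 0.9, 0.9))
  rt <- data.frame(time = c(0, 10), n_risk = c(20, 10))
  rec <- reconstruct_ipd(co, rt)
  ev <- rec[rec$event == 1, ]
  expect_true(all(ev$time <= 1))
  expect_equal(sum(rec$event == 0 & rec$time > 1 & rec$time < 10), 8)
})

test_that("initial n and total events are preserved when supplied", {
  cal <- default_calibration(c(150L, 150L))
  d <- generate_ipd(cal$arms, cal$lifetable, seed = 9)
  dig <- digitize_km(d, grid = seq(0.25, 24, 0.25),
                     risk_times = seq(0, 24, 3), endpoints = "OS")
  co <- dig$km_points[dig$km_points$arm == "C", c("time", "survival")]
  rt <- dig$risk_table[dig$risk_table$arm == "C", c("time", "n_risk")]
  true_events <- sum(d$os_event[d$arm == "C"])
  rec <- reconstruct_ipd(co, rt, total_events = true_events)
  expect_equal(nrow(rec), 150)
  expect_equal(sum(rec$event), true_events)
})

test_that("noisy coordinates are monotonized with a warning", {
  co <- data.frame(time = c(1, 2, 3), survival = c(0.8, 0.85, 0.5))
  rt <- data.frame(time = 0, n_risk = 10)
  expect_warning(rec <- reconstruct_ipd(co, rt), "monotonized")
  km <- kaplan_meier(rec)
  expect_true(all(diff(km$steps$survival) <= 1e-12))
  expect_error(suppressWarnings(
    reconstruct_ipd(co, data.frame(time = c(0, 2), n_risk = c(10, 12)))),
    "exceed")
})

test_that("coordinates-only mode is flagged and requires n_start", {
  co <- data.frame(time = 1:3, survival = c(2, 1, 0) / 3)
  expect_error(reconstruct_ipd(co), "n_start")
  rec <- reconstruct_ipd(co, n_start = 3)
  expect_identical(attr(rec, "mode"), "coords_only")
  expect_equal(sum(rec$event), 3)
})
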