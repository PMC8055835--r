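test_that("generation is reproducible and writes byte-identical CSV", {
  cal <- default_calibration(c(50L, 50L))
  d1 <- generate_ipd(cal$arms, cal$lifetable, seed = 11)
  d2 <- generate_ipd(cal$arms, cal$lifetable, seed = 11)
  expect_identical(d1, d2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_ipd(d1, f1); write_ipd(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_ipd(cal$arms, cal$lifetable, seed = 12)
  expect_false(identical(d1$os_time, d3$os_time))
  rt <- read_ipd(f1)
  expect_equal(rt$os_time, d1$os_time, tolerance = 1e-9)
})

test_that("every generated record satisfies PFS <= OS and positive times", {
  cal <- default_calibration(c(5000L, 5000L))
  d <- generate_ipd(cal$arms, cal$lifetable, seed = 2)
  expect_gte(nrow(d), 1e4)
  expect_true(all(d$pfs_time <= d$os_time + 1e-12))
  expect_true(all(d$os_time > 0 & d$pfs_time > 0))
  # death ends PFS: an OS event at equal times implies a PFS event
  same_t <- d$os_event == 1 & abs(d$os_time - d$pfs_time) < 1e-12
  expect_true(all(d$pfs_event[same_t] == 1))
})

test_that("no censoring and no cure means every OS record is an event", {
  d <- generate_ipd(exp_arm(500), lifetable = NULL, seed = 3)
  expect_true(all(d$os_event == 1))
  expect_true(all(d$pfs_event == 1))
})

test_that("exponential uncured kernel reproduces its closed-form mean", {
  d <- generate_ipd(exp_arm(40000, rate = 0.1), lifetable = NULL, seed = 4)
  expect_equal(mean(d$os_time), 10, tolerance = 0.15)
})

test_that("default calibration hits the published true survival values", {
  cal <- default_calibration()
  bg <- lifetable_survival(cal$lifetable, cal$start_age)
  ctl <- arm_true_survival(cal$arms$control, bg)
  int <- arm_true_survival(cal$arms$intervention, bg)
  expect_equal(ctl$S_os(10.3), 0.5, tolerance = 1e-6)    # median definition
  expect_equal(ctl$S_os(12), 0.382, tolerance = 1e-6)    # 1-year OS, control
  expect_equal(int$S_os(12), 0.517, tolerance = 1e-6)    # 1-year OS, intervention
  expect_equal(int$S_os(12.3), 0.5, tolerance = 1e-6)
  expect_equal(int$S_pfs(5.2), 0.5, tolerance = 1e-6)    # median PFS
  expect_equal(ctl$S_pfs(4.3), 0.5, tolerance = 1e-6)
  # tail shape: control essentially extinct by 30 months, intervention
  # retains a visible plateau
  expect_lte(ctl$S_os(30), 0.05)
  expect_gt(int$S_os(30), 1.5 * ctl$S_os(30))
  expect_gt(cal$arms$intervention$cure_fraction, 0)
})

test_that("digitized curves reproduce a hand KM calculation", {
  dig <- digitize_km(tiny_trial(), grid = c(1, 2, 3), risk_times = 0:3,
                     endpoints = "OS")
  expect_equal(dig$km_points$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # numbers at risk are counted just before each tabulated time
  expect_equal(dig$risk_table$n_risk, c(3L, 3L, 2L, 1L))
  # empty grid gives empty coordinates, and curves are non-increasing
  empty <- digitize_km(tiny_trial(), grid = numeric(0), risk_times = 0:3,
                       endpoints = "OS")
  expect_equal(nrow(empty$km_points), 0)
  tr <- shared_trial()
  dig2 <- digitize_km(tr$ipd, grid = seq(0.5, 24, 0.5))
  for (a in unique(dig2$km_points$arm)) {
    s <- dig2$km_points$survival[dig2$km_points$arm == a &
                                   dig2$km_points$endpoint == "OS"]
    expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("arm specification validates its invariants", {
  expect_error(exp_arm(1), "at least 2")
  expect_error(arm_spec("a", 10, 1.0, "exponential", c(rate = 1),
                        "lognormal", c(meanlog = 1, sdlog = 1)), "cure_fraction")
  expect_error(arm_spec("a", 10, 0, "notafamily", c(rate = 1),
                        "lognormal", c(meanlog = 1, sdlog = 1)))
  expect_error(arm_spec("a", 10, 0, "exponential", c(rate = 1, junk = 2),
                        "lognormal", c(meanlog = 1, sdlog = 1)), "length")
})
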