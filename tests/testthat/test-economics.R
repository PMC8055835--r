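fake_arm <- function(cost, qaly, lyg)
  list(costs = list(total = cost), outcomes = list(qaly = qaly, lyg = lyg))

# cheap deterministic runner: analytic curves, real economics
curve_runner <- function(os_int = 0.075, os_ctl = 0.10) {
  function(inp) {
    int <- ps_model(function(t) exp(-os_int * t), function(t) exp(-0.20 * t),
                    inp, arm = "intervention")
    ctl <- ps_model(function(t) exp(-os_ctl * t), function(t) exp(-0.22 * t),
                    inp, arm = "control")
    incremental_analysis(int, ctl)
  }
}

test_that("incremental ratios come from unrounded totals", {
  r <- incremental_analysis(fake_arm(600, 1.5, 2.0), fake_arm(500, 1.0, 1.5))
  expect_equal(r$icur, 100 / 0.5)
  expect_equal(r$icer, 100 / 0.5)
  expect_equal(r$delta_cost, 100)
  expect_identical(r$dominance, "none")
  # identical arms: undefined ratio, flagged
  r0 <- incremental_analysis(fake_arm(500, 1, 1), fake_arm(500, 1, 1))
  expect_false(r0$ratio_defined)
  expect_true(is.na(r0$icur))
  # cheaper and more effective: dominant, no ratio
  rd <- incremental_analysis(fake_arm(400, 1.5, 2), fake_arm(500, 1.0, 1.5))
  expect_identical(rd$dominance, "dominant")
  expect_true(is.na(rd$icur))
})

test_that("one-way DSA brackets the base case and sorts by width", {
  inp <- default_econ_inputs()
  run <- curve_runner()
  base <- run(inp)
  tor <- one_way_dsa(run, inp,
                     param_names = c("utility_pf", "utility_pp",
                                     "cost_atezolizumab_per10mg",
                                     "discount_rate"))
  expect_equal(attr(tor, "base_icur"), base$icur, tolerance = 1e-12)
  expect_true(all(diff(tor$width) <= 1e-12))
  # zero-width bar when low = high = base
  inp2 <- inp
  i <- match("utility_pf", inp2$params$name)
  inp2$params$low[i] <- inp2$params$high[i] <- inp2$params$value[i]
  tor2 <- one_way_dsa(run, inp2, param_names = "utility_pf")
  expect_equal(tor2$width, 0, tolerance = 1e-12)
  # raising the PP utility raises delta-QALY and so lowers the ICUR
  row <- tor[tor$name == "utility_pp", ]
  expect_gt(row$icur_low, row$icur_high)
})

test_that("DSA evaluated at the base value reproduces the base ICUR", {
  inp <- default_econ_inputs()
  run <- curve_runner()
  base <- run(inp)
  i <- match("utility_pp", inp$params$name)
  inp_deg <- inp
  inp_deg$params$low[i] <- inp_deg$params$high[i] <- inp_deg$params$value[i]
  tor <- one_way_dsa(run, inp_deg, param_names = "utility_pp")
  expect_equal(tor$icur_low, base$icur, tolerance = 1e-12)
  expect_equal(tor$icur_high, base$icur, tolerance = 1e-12)
})

test_that("PSA draws follow the ledger distributions", {
  inp <- default_econ_inputs()
  set.seed(5)
  s <- psmcure:::sample_psa_inputs(inp, 4000)
  pr <- inp$params
  for (nm in c("utility_pf", "cost_death", "duration_anemia")) {
    i <- match(nm, pr$name)
    se <- (pr$high[i] - pr$low[i]) / 3.92
    expect_lt(abs(mean(s[, nm]) - pr$value[i]), 4 * se / sqrt(4000) + 1e-9)
    expect_equal(stats::sd(s[, nm]), se, tolerance = 0.08)
  }
  # the stated moment rule for the PF utility: SE ~ 0.05383
  expect_equal((0.883 - 0.672) / 3.92, 0.05383, tolerance = 1e-3)
  # fixed inputs never vary
  expect_true(all(s[, "discount_rate"] == 0.03))
  # disutilities sampled on the magnitude and negated
  expect_true(all(s[, "disutility_anemia"] < 0))
  expect_true(all(s[, "disutility_anemia"] > -1))
  # utilities and risks stay inside [0, 1]
  expect_true(all(s[, "utility_pp"] >= 0 & s[, "utility_pp"] <= 1))
  expect_true(all(s[, "risk_ac_anemia"] >= 0 & s[, "risk_ac_anemia"] <= 1))
  # costs are non-negative under the gamma
  expect_true(all(s[, "cost_death"] >= 0))
})

test_that("PSA is reproducible and collapses to the base case when fixed", {
  inp <- default_econ_inputs()
  run <- curve_runner()
  p1 <- psa(run, inp, n_draws = 60, seed = 9)
  p2 <- psa(run, inp, n_draws = 60, seed = 9)
  expect_identical(p1$draws, p2$draws)
  p3 <- psa(run, inp, n_draws = 60, seed = 10)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))
  # all-fixed ledger: every draw equals the deterministic result
  inp_fix <- inp
  inp_fix$params$dist <- "fixed"
  pf <- psa(run, inp_fix, n_draws = 10, seed = 1)
  base <- run(inp)
  expect_true(all(abs(pf$draws$delta_cost - base$delta_cost) < 1e-9))
  expect_true(all(abs(pf$draws$delta_qaly - base$delta_qaly) < 1e-9))
})

test_that("CEAC summarises net monetary benefit correctly", {
  draws <- data.frame(delta_cost = c(-10, 20, 30, -5),
                      delta_qaly = c(0.1, 0.2, -0.1, 0.3))
  x <- list(draws = draws)
  class(x) <- "ps_psa"
  cc <- ceac(x, lambda = c(0, 100, 1000))
  expect_true(all(cc$p_ce >= 0 & cc$p_ce <= 1))
  # lambda = 0: NMB > 0 means negative incremental cost
  expect_equal(cc$p_ce[1], mean(draws$delta_cost < 0))
  expect_equal(nmb(x, 100), 100 * draws$delta_qaly - draws$delta_cost)
  # all draws cheaper and more effective: curve pinned at 1
  all_dom <- list(draws = data.frame(delta_cost = c(-1, -2),
                                     delta_qaly = c(0.1, 0.2)))
  class(all_dom) <- "ps_psa"
  expect_true(all(ceac(all_dom)$p_ce == 1))
  # monotone non-decreasing in lambda when every draw gains QALYs
  pos <- list(draws = data.frame(delta_cost = stats::runif(50, 0, 100),
                                 delta_qaly = stats::runif(50, 0.01, 0.5)))
  class(pos) <- "ps_psa"
  expect_true(all(diff(ceac(pos)$p_ce) >= 0))
})

test_that("scenario analysis overrides utilities and moves the ICUR as expected", {
  inp <- default_econ_inputs()
  runners <- list(a = curve_runner(), b = curve_runner(0.07, 0.10))
  sc <- scenario_analysis(runners, c(utility_pf = 0.673, utility_pp = 0.473),
                          inp)
  expect_equal(nrow(sc), 4)
  # empty override set reproduces the base case
  sc0 <- scenario_analysis(runners["a"], stats::setNames(numeric(0),
                                                         character(0)), inp)
  expect_equal(sc0$icur[1], sc0$icur[2], tolerance = 1e-12)
  # lowering the PF utility with positive delta-QALY raises the ICUR
  for (v in unique(sc$variant)) {
    sub <- sc[sc$variant == v, ]
    expect_gt(sub$icur[sub$case == "scenario"], sub$icur[sub$case == "base"])
  }
  expect_error(scenario_analysis(runners, c(not_an_input = 1), inp),
               "unknown")
})
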