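test_that("cycle grid covers the horizon and discounts correctly", {
  g <- cycle_grid()
  expect_equal(g$n_cycles, 44)
  expect_gte(g$n_cycles * 21, 2.5 * 365.25)
  # discount factor at exactly one year is 1/1.03
  g1 <- cycle_grid(cycle_length_days = 365.25, horizon_years = 2)
  expect_equal(g1$discount[2], 1 / 1.03, tolerance = 1e-12)
  expect_error(cycle_grid(discount_rate_annual = 0.06), "0, 0.05")
  gh <- cycle_grid(half_cycle = TRUE)
  expect_equal(gh$time_days[1], 10.5)
})

test_that("state occupancy partitions the cohort and respects clamping", {
  g <- cycle_grid()
  occ <- compute_membership(function(t) exp(-0.08 * t),
                            function(t) exp(-0.20 * t), g)
  expect_true(all(abs(occ$pf + occ$pp + occ$dead - 1) < 1e-9))
  expect_true(all(diff(occ$dead) >= -1e-12))
  expect_true(all(occ$pp >= 0))
  # (S_os, S_pfs) = (0.8, 0.5) -> (0.5, 0.3, 0.2)
  occ1 <- compute_membership(rep(0.8, g$n_cycles), rep(0.5, g$n_cycles), g)
  expect_equal(unlist(occ1[2, c("pf", "pp", "dead")]),
               c(pf = 0.5, pp = 0.3, dead = 0.2), tolerance = 1e-12)
  # identical curves leave nobody post-progression
  occ2 <- compute_membership(function(t) exp(-0.1 * t),
                             function(t) exp(-0.1 * t), g)
  expect_true(all(occ2$pp < 1e-12))
  # PFS above OS is clamped to OS with pp = 0 there
  occ3 <- compute_membership(rep(0.6, g$n_cycles), rep(0.7, g$n_cycles), g)
  expect_true(all(occ3$pf == 0.6 & occ3$pp == 0))
  expect_equal(attr(occ3, "n_clamped"), g$n_cycles)
  expect_error(compute_membership(rep(1.2, g$n_cycles),
                                  rep(0.5, g$n_cycles), g), "outside")
})

test_that("regimen cycle costs reproduce the ledger arithmetic", {
  inp <- default_econ_inputs()
  # atezolizumab 1200 mg at 77.46 per 10 mg
  expect_equal(regimen_cycle_cost("atezolizumab", inp)[["total"]],
               1200 / 10 * 77.46, tolerance = 1e-9)
  expect_equal(regimen_cycle_cost("atezolizumab", inp)[["total"]], 9295.20,
               tolerance = 1e-9)
  # carboplatin via Calvert: AUC 5 x (70 + 25) = 475 mg -> 29.355
  ce <- regimen_cycle_cost("carboplatin_etoposide", inp)
  expect_equal(ce[["carboplatin"]], 475 / 50 * 3.09, tolerance = 1e-9)
  expect_equal(ce[["carboplatin"]], 29.355, tolerance = 1e-9)
  # etoposide 100 mg/m2 x 1.86 m2 on 3 dosing days
  expect_equal(ce[["etoposide"]], 100 * 1.86 * 3 / 10 * 0.66, tolerance = 1e-9)
  # vincristine flat 2 mg at 4.88/mg
  expect_equal(regimen_cycle_cost("cav", inp)[["vincristine"]], 9.76,
               tolerance = 1e-9)
  expect_error(regimen_cycle_cost("nope", inp))
})

test_that("expected QALYs and life-years follow the closed forms", {
  inp <- default_econ_inputs()
  # undiscounted full year alive in PF with no AEs: 0.84 QALY, 1 LY
  g <- cycle_grid(cycle_length_days = 365.25 / 10, horizon_years = 1,
                  discount_rate_annual = 0)
  occ <- compute_membership(rep(1, g$n_cycles), rep(1, g$n_cycles), g)
  inp0 <- inp
  inp0$params$value[grepl("^risk_", inp0$params$name)] <- 0
  inp0 <- econ_override(inp0, c(discount_rate = 0))
  out <- expected_qalys_lys(occ, inp0, g, "intervention")
  expect_equal(out$lyg, 1, tolerance = 1e-9)
  expect_equal(out$qaly, 0.84, tolerance = 1e-9)
  # u_pf = u_pp = 1 and no discounting makes QALYs equal LYs
  inp1 <- econ_override(inp0, c(utility_pf = 1, utility_pp = 1))
  out1 <- expected_qalys_lys(occ, inp1, g, "intervention")
  expect_equal(out1$qaly, out1$lyg, tolerance = 1e-12)
  # anemia decrement: risk 0.14 x |disutility| 0.09 x 21/365.25 days
  dec <- 0.14 * 0.09 * 21 / 365.25
  full <- expected_qalys_lys(occ, inp, g, "intervention")
  anemia_share <- 0.14 * 0.09 * 21 / 365.25
  expect_equal(anemia_share, 0.000724, tolerance = 1e-3)
  expect_gt(full$ae_decrement, anemia_share)  # all five AEs included
  # utilities outside [0,1] rejected
  expect_error(expected_qalys_lys(occ, econ_override(inp, c(utility_pf = 1.2)),
                                  g, "intervention"), "0, 1")
})

test_that("costs discount, scale linearly and split by category", {
  inp <- default_econ_inputs()
  g <- cycle_grid()
  occ <- compute_membership(function(t) exp(-0.08 * t),
                            function(t) exp(-0.2 * t), g)
  ctl <- expected_costs(occ, inp, g, "control")
  int <- expected_costs(occ, inp, g, "intervention")
  expect_gt(int$drug, ctl$drug)          # atezolizumab acquisition
  expect_gt(int$total, ctl$total)
  # homogeneity: doubling every unit cost doubles the total
  inp2 <- inp
  cost_rows <- inp2$params$group %in% c("unit_cost", "cost", "ae_cost")
  inp2$params$value[cost_rows] <- inp2$params$value[cost_rows] * 2
  inp2$params$high[cost_rows] <- inp2$params$high[cost_rows] * 4
  int2 <- expected_costs(occ, inp2, g, "intervention")
  expect_equal(int2$total, 2 * int$total, tolerance = 1e-9)
  # discounting can only lower a non-negative stream; equal at rate 0
  g0 <- cycle_grid(discount_rate_annual = 0)
  occ0 <- compute_membership(function(t) exp(-0.08 * t),
                             function(t) exp(-0.2 * t), g0)
  int0 <- expected_costs(occ0, econ_override(inp, c(discount_rate = 0)),
                         g0, "intervention")
  expect_gt(int0$total, int$total)
  # death costs: everyone eventually incurs at most one
  expect_lte(ctl$death / econ_value(inp, "cost_death"), 1)
})

test_that("ps_model composes the pieces and reports a trace", {
  inp <- default_econ_inputs()
  m <- ps_model(function(t) exp(-0.09 * t), function(t) exp(-0.22 * t),
                inp, arm = "intervention")
  expect_s3_class(m, "ps_model")
  expect_equal(nrow(m$trace), m$grid$n_cycles)
  expect_equal(sum(m$trace$qaly_inc), m$outcomes$qaly + m$outcomes$ae_decrement,
               tolerance = 1e-9)
  expect_equal(m$costs$total,
               sum(attr(m$costs, "per_cycle")), tolerance = 1e-9)
  # raising the PF utility strictly raises QALYs
  m2 <- ps_model(function(t) exp(-0.09 * t), function(t) exp(-0.22 * t),
                 econ_override(inp, c(utility_pf = 0.9)),
                 arm = "intervention")
  expect_gt(m2$outcomes$qaly, m$outcomes$qaly)
})
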