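test_that("exponential MLE matches the censored closed form", {
  # uncensored times (1,2,3): rate = events / total time = 3/6
  f <- fit_parametric(c(1, 2, 3), c(1, 1, 1), "exponential")
  expect_equal(unname(coef(f)), 0.5, tolerance = 1e-6)
  # last observation censored: rate = 2/6
  f2 <- fit_parametric(c(1, 2, 3), c(1, 1, 0), "exponential")
  expect_equal(unname(coef(f2)), 2 / 6, tolerance = 1e-6)
  expect_true(f2$converged)
  # log-likelihood at the MLE equals the closed form
  lam <- 2 / 6
  expect_equal(f2$loglik, 2 * log(lam) - lam * 6, tolerance = 1e-8)
})

test_that("AIC follows -2*loglik + 2k and logLik() carries df", {
  tr <- shared_trial()
  d <- tr$ipd[tr$ipd$arm == "C", ]
  f <- fit_parametric(d$os_time, d$os_event, "weibull")
  expect_equal(f$aic, -2 * f$loglik + 2 * 2, tolerance = 1e-10)
  expect_equal(AIC(f), f$aic, tolerance = 1e-10)
  expect_equal(attr(logLik(f), "df"), 2)
})

test_that("formula interface with Surv() reproduces the vector interface", {
  tr <- shared_trial()
  d <- tr$ipd[tr$ipd$arm == "C", ]
  f1 <- fit_parametric(d$os_time, d$os_event, "gompertz")
  f2 <- fit_parametric(survival::Surv(os_time, os_event) ~ 1, data = d,
                       family = "gompertz")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("all five families recover their parameters at n = 2000", {
  true <- list(
    exponential = c(rate = 0.09),
    weibull = c(shape = 1.5, scale = 13),
    gompertz = c(shape = 0.12, rate = 0.03),
    loglogistic = c(shape = 2.4, scale = 9),
    lognormal = c(meanlog = 2.2, sdlog = 0.8)
  )
  set.seed(101)
  for (nm in names(true)) {
    fam <- surv_family(nm)
    # bias of the estimator, averaged over replicates
    est <- rowMeans(matrix(vapply(1:4, function(i) {
      tt <- fam$r(2000, true[[nm]])
      coef(fit_parametric(tt, rep(1, 2000), nm))
    }, numeric(length(true[[nm]]))), nrow = length(true[[nm]])))
    rel <- abs(est - true[[nm]]) / pmax(abs(true[[nm]]), 0.05)
    expect_true(all(rel <= 0.05),
                info = paste(nm, paste(signif(rel, 3), collapse = "/")))
  }
})

test_that("the optimum beats random admissible parameter vectors", {
  tr <- shared_trial()
  d <- tr$ipd[tr$ipd$arm == "A+C", ]
  f <- fit_parametric(d$os_time, d$os_event, "weibull")
  fam <- f$family
  ll <- function(p) sum(log(pmax(fam$f(d$os_time[d$os_event == 1], p), 1e-300))) +
    sum(log(pmax(fam$S(d$os_time[d$os_event == 0], p), 1e-300)))
  set.seed(7)
  for (i in 1:50) {
    p <- c(shape = exp(stats::runif(1, -1.5, 1.5)),
           scale = exp(stats::runif(1, 0.5, 4)))
    expect_gte(f$loglik + 1e-6, ll(p))
  }
})

test_that("fits agree with flexsurv on the same data", {
  skip_if_not_installed("flexsurv")
  tr <- shared_trial()
  d <- tr$ipd[tr$ipd$arm == "C", ]
  for (pair in list(c("gompertz", "gompertz"), c("weibull", "weibull"),
                    c("lognormal", "lnorm"))) {
    mine <- fit_parametric(d$os_time, d$os_event, pair[1])
    ref <- flexsurv::flexsurvreg(survival::Surv(os_time, os_event) ~ 1,
                                 data = d, dist = pair[2])
    expect_equal(mine$loglik, ref$loglik, tolerance = 1e-4)
    expect_equal(unname(coef(mine)), unname(ref$res[, "est"]),
                 tolerance = 1e-3)
  }
})

test_that("model selection picks lowest AIC with a fewer-parameter tie-break", {
  mk <- function(name, aic, k, conv = TRUE)
    structure(list(family = list(name = name), aic = aic, k = k,
                   loglik = -(aic - 2 * k) / 2, converged = conv),
              class = "psm_parfit")
  fits <- list(a = mk("a", 100, 2), b = mk("b", 90, 2), c = mk("c", 95, 2))
  expect_equal(select_model(fits)$best$family$name, "b")
  # non-converged fits are excluded even with the lowest AIC
  fits$d <- mk("d", 50, 2, conv = FALSE)
  expect_equal(select_model(fits)$best$family$name, "b")
  # exact tie goes to fewer parameters
  tied <- list(two = mk("two", 90, 2), one = mk("one", 90, 1))
  expect_message(sel <- select_model(tied), "tie")
  expect_equal(sel$best$family$name, "one")
})

test_that("the generating family wins the AIC ranking in most seeds", {
  wins <- 0
  for (seed in 1:10) {
    sp <- arm_spec("A", 1200, 0, "gompertz", c(shape = 0.15, rate = 0.03),
                   "lognormal", c(meanlog = 1.6, sdlog = 0.8),
                   accrual_months = 8, admin_censor_months = 30,
                   dropout_rate = 0)
    d <- generate_ipd(sp, lifetable = NULL, seed = seed)
    sel <- fit_all_parametric(d$os_time, d$os_event)$selection
    if (sel$best$family$name == "gompertz") wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_parametric(c(1, 2), c(0, 0), "exponential"), "no events")
  expect_error(fit_parametric(c(-1, 2), c(1, 1), "exponential"), "positive")
  expect_error(fit_parametric(c(1, 2, 3), c(1, 0, 0), "weibull"),
               "at least")
})
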