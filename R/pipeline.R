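#' Run the full partitioned-survival cost-effectiveness pipeline
#'
#' End-to-end orchestration: simulate the calibrated two-arm trial,
#' digitize its Kaplan-Meier curves and reconstruct pseudo-IPD, fit the
#' five standard parametric families per arm and endpoint (plus the
#' mixture cure model for intervention-arm OS), apply background
#' mortality, run the three-state partitioned survival model under both
#' intervention-arm extrapolation variants -- \code{"mixture_cure"}
#' (model 1) and \code{"standard_parametric"} (model 2); the control arm
#' always uses the standard parametric extrapolation -- and perform the
#' one-way DSA, the PSA with CEAC, and the utility scenario analysis.
#' The whole run is reproducible from the seed.
#'
#' Base-case extrapolation families are Gompertz for OS and log-normal
#' for PFS (restricted Gompertz as the cure model's uncured kernel); the
#' AIC ranking of all candidate fits is emitted for inspection alongside.
#'
#' @param seed integer seed driving simulation and PSA.
#' @param n_per_arm patients per arm (intervention, control).
#' @param inputs economic inputs ledger.
#' @param psa_draws Monte Carlo draws for the PSA (0 skips it).
#' @param run_dsa,run_scenario logical switches for the slower stages.
#' @param reconstruct fit on pseudo-IPD reconstructed from digitized
#'   curves (TRUE, the production path) or directly on the simulated IPD.
#' @param scenario_utilities named overrides for the scenario analysis.
#' @param out_dir optional directory; when given, the report pack is also
#'   written as CSV files.
#' @return object of class \code{"psm_report"}: list with \code{ipd},
#'   \code{km_summary}, \code{ph}, \code{fit_ranking}, \code{fits},
#'   \code{survival_grid}, \code{results} (Table-2-shaped data frame for
#'   both variants), \code{ce} (both \code{ce_result}s), \code{tornado},
#'   \code{psa}, \code{ceac}, \code{scenario}, \code{manifest}.
#' @examples
#' \donttest{
#' rep <- run_pipeline(seed = 1, psa_draws = 200)
#' rep$results
#' }
#' @export
run_pipeline <- function(seed = 1, n_per_arm = c(201L, 202L),
                         inputs = default_econ_inputs(), psa_draws = 1000,
                         run_dsa = TRUE, run_scenario = TRUE,
                         reconstruct = TRUE,
                         scenario_utilities = c(utility_pf = 0.673,
                                                utility_pp = 0.473),
                         out_dir = NULL) {
  validate_econ_inputs(inputs)
  cal <- default_calibration(n_per_arm)
  ipd <- generate_ipd(cal$arms, cal$lifetable, cal$start_age, seed = seed)
  bg <- lifetable_survival(cal$lifetable, cal$start_age)
  arms <- unname(vapply(cal$arms, `[[`, "", "name"))  # intervention, control

  # -- data preparation: digitize + reconstruct (the production path) ----
  fit_data <- list()
  if (reconstruct) {
    dig <- digitize_km(ipd, grid = seq(0.25, 24, by = 0.25),
                       risk_times = seq(0, 24, by = 3))
    rec <- reconstruct_trial(dig$km_points, dig$risk_table)
    for (a in arms) for (ep in c("OS", "PFS"))
      fit_data[[paste(a, ep)]] <-
        rec[rec$arm == a & rec$endpoint == ep, c("time", "event")]
  } else {
    for (a in arms) for (ep in c("OS", "PFS")) {
      cols <- paste0(tolower(ep), c("_time", "_event"))
      sub <- ipd[ipd$arm == a, ]
      fit_data[[paste(a, ep)]] <-
        data.frame(time = sub[[cols[1]]], event = sub[[cols[2]]])
    }
  }

  # -- survival fitting ---------------------------------------------------
  fits <- list(); ranking <- list()
  for (key in names(fit_data)) {
    d <- fit_data[[key]]
    all_fits <- fit_all_parametric(d$time, d$event)
    fits[[key]] <- all_fits$fits
    rk <- all_fits$selection$ranking
    rk$arm_endpoint <- key
    ranking[[key]] <- rk
  }
  cure_d <- fit_data[[paste(arms[1], "OS")]]
  cure_fit <- fit_mixture_cure(cure_d$time, cure_d$event,
                               family = "gompertz", background = bg,
                               restricted = TRUE)
  fits[["cure OS"]] <- cure_fit

  # -- extrapolations on the cycle grid ----------------------------------
  S_par <- function(key, fam) {
    f <- fits[[key]][[fam]]
    adj <- apply_background_mortality(f, bg)
    adj$S
  }
  curves <- list(
    intervention = list(
      os_parametric = S_par(paste(arms[1], "OS"), "gompertz"),
      os_cure = function(t) predict(cure_fit, t),
      pfs = S_par(paste(arms[1], "PFS"), "lognormal")
    ),
    control = list(
      os = S_par(paste(arms[2], "OS"), "gompertz"),
      pfs = S_par(paste(arms[2], "PFS"), "lognormal")
    )
  )

  runner <- function(mode) {
    S_int_os <- if (mode == "mixture_cure") curves$intervention$os_cure
                else curves$intervention$os_parametric
    function(inp) {
      int <- ps_model(S_int_os, curves$intervention$pfs, inp,
                      arm = "intervention")
      ctl <- ps_model(curves$control$os, curves$control$pfs, inp,
                      arm = "control")
      incremental_analysis(int, ctl)
    }
  }
  runners <- list(mixture_cure = runner("mixture_cure"),
                  standard_parametric = runner("standard_parametric"))

  ce <- lapply(runners, function(r) r(inputs))
  base_models <- lapply(names(runners), function(mode) {
    S_int_os <- if (mode == "mixture_cure") curves$intervention$os_cure
                else curves$intervention$os_parametric
    list(intervention = ps_model(S_int_os, curves$intervention$pfs, inputs,
                                 arm = "intervention"),
         control = ps_model(curves$control$os, curves$control$pfs, inputs,
                            arm = "control"))
  })
  names(base_models) <- names(runners)

  results <- do.call(rbind, lapply(names(ce), function(m) {
    x <- ce[[m]]
    data.frame(model = m,
               group = c("intervention", "control", "incremental"),
               cost = c(x$arms$cost, x$delta_cost),
               qaly = c(x$arms$qaly, x$delta_qaly),
               lyg = c(x$arms$lyg, x$delta_lyg),
               icur = c(NA, NA, x$icur), icer = c(NA, NA, x$icer))
  }))

  tornado <- if (run_dsa) lapply(runners, one_way_dsa, inputs = inputs)
             else NULL
  psa_res <- ceac_res <- NULL
  if (psa_draws > 0) {
    psa_res <- lapply(seq_along(runners), function(i)
      psa(runners[[i]], inputs, n_draws = psa_draws, seed = seed + i))
    names(psa_res) <- names(runners)
    ceac_res <- lapply(psa_res, ceac)
  }
  scenario <- if (run_scenario)
    scenario_analysis(runners, scenario_utilities, inputs) else NULL

  grid <- cycle_grid(discount_rate_annual =
                       econ_value(inputs, "discount_rate"))
  survival_grid <- do.call(rbind, list(
    data.frame(arm = arms[1], endpoint = "OS", model = "mixture_cure",
               time = grid$time_months,
               survival = curves$intervention$os_cure(grid$time_months)),
    data.frame(arm = arms[1], endpoint = "OS", model = "gompertz",
               time = grid$time_months,
               survival = curves$intervention$os_parametric(grid$time_months)),
    data.frame(arm = arms[1], endpoint = "PFS", model = "lognormal",
               time = grid$time_months,
               survival = curves$intervention$pfs(grid$time_months)),
    data.frame(arm = arms[2], endpoint = "OS", model = "gompertz",
               time = grid$time_months,
               survival = curves$control$os(grid$time_months)),
    data.frame(arm = arms[2], endpoint = "PFS", model = "lognormal",
               time = grid$time_months,
               survival = curves$control$pfs(grid$time_months))
  ))

  km_summary <- do.call(rbind, lapply(arms, function(a)
    do.call(rbind, lapply(c("OS", "PFS"), function(ep) {
      km <- kaplan_meier(ipd, ep, a)
      data.frame(arm = a, endpoint = ep, n = km$n,
                 events = sum(km$steps$n_event),
                 median = km$median,
                 surv_12m = summary(km, times = 12)$survival)
    }))))
  ph <- list(OS = test_ph(ipd, "OS"), PFS = test_ph(ipd, "PFS"))

  out <- structure(list(
    ipd = ipd, km_summary = km_summary, ph = ph,
    fit_ranking = do.call(rbind, c(ranking, make.row.names = FALSE)),
    fits = fits, curves = curves, models = base_models,
    survival_grid = survival_grid,
    results = results, ce = ce, tornado = tornado,
    psa = psa_res, ceac = ceac_res, scenario = scenario,
    runners = runners,
    manifest = list(seed = seed, n_per_arm = n_per_arm,
                    psa_draws = psa_draws, reconstruct = reconstruct,
                    r_version = R.version.string,
                    package_version =
                      as.character(utils::packageVersion("psmcure")))
  ), class = "psm_report")
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.psm_report <- function(x, ...) {
  cat("Partitioned-survival cost-effectiveness report (seed",
      x$manifest$seed, ")\n\n")
  res <- x$results
  res$cost <- round(res$cost); res$qaly <- round(res$qaly, 3)
  res$lyg <- round(res$lyg, 3)
  res$icur <- round(res$icur); res$icer <- round(res$icer)
  print(res, row.names = FALSE)
  if (!is.null(x$ceac)) {
    p <- vapply(x$ceac, function(cc)
      cc$p_ce[match(1e5, cc$lambda)], 0)
    cat("\nP(cost-effective at US$100,000/QALY): ",
        paste(names(p), round(100 * p, 1), "%", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write a report pack to CSV files
#'
#' Emits the tables of a \code{\link{run_pipeline}} report as plain CSV:
#' \code{ipd.csv}, \code{km_summary.csv}, \code{fits.csv},
#' \code{survival_grid.csv}, \code{results.csv}, \code{tornado_*.csv},
#' \code{psa_draws_*.csv}, \code{ceac_*.csv}, \code{scenario.csv},
#' \code{manifest.yaml}.
#'
#' @param report a \code{psm_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm)
    utils::write.csv(df, file.path(dir, nm), row.names = FALSE, quote = FALSE)
  write_ipd(report$ipd, file.path(dir, "ipd.csv"))
  wr(report$km_summary, "km_summary.csv")
  wr(report$fit_ranking, "fits.csv")
  wr(report$survival_grid, "survival_grid.csv")
  wr(report$results, "results.csv")
  for (m in names(report$tornado %||% list()))
    wr(as.data.frame(report$tornado[[m]]), paste0("tornado_", m, ".csv"))
  for (m in names(report$psa %||% list())) {
    wr(report$psa[[m]]$draws, paste0("psa_draws_", m, ".csv"))
    wr(as.data.frame(report$ceac[[m]]), paste0("ceac_", m, ".csv"))
  }
  if (!is.null(report$scenario)) wr(report$scenario, "scenario.csv")
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
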