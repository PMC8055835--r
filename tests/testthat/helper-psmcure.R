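# Shared fixtures, built in code and cached across test files.

.shared <- new.env(parent = emptyenv())

# moderate-size calibrated trial used by several files
shared_trial <- function() {
  if (is.null(.shared$trial)) {
    cal <- default_calibration(c(400L, 400L))
    .shared$trial <- list(
      cal = cal,
      ipd = generate_ipd(cal$arms, cal$lifetable, cal$start_age, seed = 42),
      bg = lifetable_survival(cal$lifetable, cal$start_age)
    )
  }
  .shared$trial
}

# small end-to-end pipeline run reused by pipeline/economics tests
shared_report <- function() {
  if (is.null(.shared$report)) {
    .shared$report <- run_pipeline(seed = 7, n_per_arm = c(150L, 150L),
                                   psa_draws = 200, run_dsa = FALSE,
                                   run_scenario = FALSE)
  }
  .shared$report
}

# three uncensored deaths at t = 1, 2, 3 — the hand-KM fixture
tiny_trial <- function(arm = "A") {
  data.frame(patient_id = paste0(arm, 1:3), arm = arm,
             os_time = c(1, 2, 3), os_event = 1L,
             pfs_time = c(1, 2, 3), pfs_event = 1L,
             stringsAsFactors = FALSE)
}

# one-arm spec with simple exponential OS, handy for oracles
exp_arm <- function(n, rate = 0.1, name = "X", cure = 0,
                    admin = 1e6, accrual = 1, dropout = 0) {
  arm_spec(name, n, cure, "exponential", c(rate = rate),
           "lognormal", c(meanlog = 1, sdlog = 0.5),
           accrual_months = accrual, admin_censor_months = admin,
           dropout_rate = dropout)
}
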