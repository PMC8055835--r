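#' Cycle grid for the partitioned survival model
#'
#' The model runs on 21-day cycles over a 2.5-year lifetime horizon
#' (\eqn{\lceil 2.5 \times 365.25 / 21 \rceil = 44} cycles), with costs and
#' outcomes discounted at 3\% per year. State membership is evaluated at
#' cycle starts by default; \code{half_cycle = TRUE} evaluates at cycle
#' midpoints instead.
#'
#' @param cycle_length_days cycle length in days.
#' @param horizon_years model horizon in years.
#' @param discount_rate_annual annual discount rate, in [0, 0.05].
#' @param half_cycle evaluate state membership at cycle midpoints.
#' @return object of class \code{"cycle_grid"}: list with
#'   \code{n_cycles}, \code{time_days} (evaluation time per cycle),
#'   \code{discount} (per-cycle discount factors), and the settings.
#' @export
cycle_grid <- function(cycle_length_days = 21, horizon_years = 2.5,
                       discount_rate_annual = 0.03, half_cycle = FALSE) {
  if (discount_rate_annual < 0 || discount_rate_annual > 0.05)
    stop("discount rate must lie in [0, 0.05]")
  n <- ceiling(horizon_years * 365.25 / cycle_length_days)
  t_start <- (seq_len(n) - 1) * cycle_length_days
  t_eval <- t_start + if (half_cycle) cycle_length_days / 2 else 0
  structure(list(
    n_cycles = n, cycle_length_days = cycle_length_days,
    horizon_years = horizon_years,
    discount_rate_annual = discount_rate_annual,
    half_cycle = half_cycle,
    time_days = t_eval,
    time_months = t_eval / 30.4375,
    years = t_eval / 365.25,
    discount = (1 + discount_rate_annual)^(-(t_eval / 365.25))
  ), class = "cycle_grid")
}

#' @export
print.cycle_grid <- function(x, ...) {
  cat("Cycle grid:", x$n_cycles, "cycles of", x$cycle_length_days,
      "days over", x$horizon_years, "years; discount",
      x$discount_rate_annual * 100, "%/yr",
      if (x$half_cycle) "(midpoint evaluation)" else "", "\n")
  invisible(x)
}

#' Per-cycle state occupancy from OS and PFS curves
#'
#' Partitioned-survival bookkeeping: progression-free membership is the
#' PFS curve (clamped from above by OS where fitted curves cross),
#' post-progression is the difference between OS and PFS, and dead is the
#' OS complement:
#' \eqn{pf_k = \min(S_{PFS}(t_k), S_{OS}(t_k))},
#' \eqn{pp_k = S_{OS}(t_k) - pf_k}, \eqn{dead_k = 1 - S_{OS}(t_k)}.
#'
#' @param S_os,S_pfs survival probabilities on the cycle grid (vectors of
#'   length \code{grid$n_cycles}), or functions of time in months.
#' @param grid a \code{\link{cycle_grid}}.
#' @return object of class \code{"state_occupancy"}: data frame with
#'   columns \code{cycle, time_days, pf, pp, dead}; attribute
#'   \code{"n_clamped"} counts cycles where PFS exceeded OS.
#' @examples
#' g <- cycle_grid()
#' occ <- compute_membership(function(t) exp(-0.05 * t),
#'                           function(t) exp(-0.12 * t), g)
#' stopifnot(all(abs(occ$pf + occ$pp + occ$dead - 1) < 1e-12))
#' @export
compute_membership <- function(S_os, S_pfs, grid) {
  if (is.function(S_os)) S_os <- S_os(grid$time_months)
  if (is.function(S_pfs)) S_pfs <- S_pfs(grid$time_months)
  if (length(S_os) != grid$n_cycles || length(S_pfs) != grid$n_cycles)
    stop("curves must be evaluated on the cycle grid")
  if (any(S_os < -1e-9 | S_os > 1 + 1e-9 | S_pfs < -1e-9 | S_pfs > 1 + 1e-9))
    stop("survival values outside [0, 1]")
  S_os <- pmin(pmax(S_os, 0), 1); S_pfs <- pmin(pmax(S_pfs, 0), 1)
  clamped <- S_pfs > S_os + 1e-12
  pf <- pmin(S_pfs, S_os)
  out <- data.frame(cycle = seq_len(grid$n_cycles),
                    time_days = grid$time_days,
                    pf = pf, pp = S_os - pf, dead = 1 - S_os)
  attr(out, "n_clamped") <- sum(clamped)
  class(out) <- c("state_occupancy", "data.frame")
  out
}

#' Drug-acquisition cost of one treatment cycle
#'
#' Doses follow the trial regimens: atezolizumab 1,200 mg flat;
#' carboplatin by the Calvert formula (AUC x (CrCl + 25));
#' etoposide 100 mg/m2/day on 3 days of each 21-day cycle;
#' topotecan 1.5 mg/m2/day on days 1-5; CAV as cyclophosphamide
#' 1,000 mg/m2 + doxorubicin 45 mg/m2 + vincristine 2 mg flat on day 1.
#' Cost = dose / unit size x unit cost (linear pricing, no wastage).
#'
#' @param regimen one of \code{"atezolizumab"},
#'   \code{"carboplatin_etoposide"}, \code{"topotecan"}, \code{"cav"}.
#' @param inputs an \code{\link{default_econ_inputs}} object (unit costs
#'   and patient constants are read from it).
#' @return named numeric vector of per-component costs (US$) for one
#'   cycle, with a \code{"total"} element.
#' @examples
#' regimen_cycle_cost("atezolizumab", default_econ_inputs())  # 9295.20
#' @export
regimen_cycle_cost <- function(regimen = c("atezolizumab",
                                           "carboplatin_etoposide",
                                           "topotecan", "cav"),
                               inputs = default_econ_inputs()) {
  regimen <- match.arg(regimen)
  pt <- inputs$constants$patient
  rg <- inputs$constants$regimens
  if (any(unlist(pt) <= 0)) stop("patient constants must be positive")
  v <- function(nm) econ_value(inputs, nm)
  out <- switch(regimen,
    atezolizumab = c(
      atezolizumab = rg$atezolizumab_mg / 10 * v("cost_atezolizumab_per10mg")),
    carboplatin_etoposide = c(
      carboplatin = rg$carboplatin_auc * (pt$crcl_ml_min + 25) / 50 *
        v("cost_carboplatin_per50mg"),
      etoposide = rg$etoposide_mg_m2 * pt$bsa_m2 * rg$etoposide_days / 10 *
        v("cost_etoposide_per10mg")),
    topotecan = c(
      topotecan = rg$topotecan_mg_m2 * pt$bsa_m2 * rg$topotecan_days / 0.1 *
        v("cost_topotecan_per0.1mg")),
    cav = c(
      cyclophosphamide = rg$cyclophosphamide_mg_m2 * pt$bsa_m2 / 100 *
        v("cost_cyclophosphamide_per100mg"),
      doxorubicin = rg$doxorubicin_mg_m2 * pt$bsa_m2 / 10 *
        v("cost_doxorubicin_per10mg"),
      vincristine = rg$vincristine_mg / 1 * v("cost_vincristine_per1mg"))
  )
  c(out, total = sum(out))
}

#' Expected discounted costs by category
#'
#' Accumulates per-cycle costs weighted by state occupancy and discounted
#' at the grid's annual rate: first-line chemotherapy (cycles 1-4, both
#' arms) and atezolizumab (every cycle while progression-free,
#' intervention arm) weighted by PF membership, with first/subsequent
#' administration fees; supportive care for all alive patients;
#' second-line chemotherapy as a lump sum (4 cycles of topotecan or CAV by
#' arm-specific uptake) at incident progression; terminal care at incident
#' death; and adverse-event management applied once at cycle 1 by default
#' (\code{ae_once = FALSE} spreads it over the chemotherapy cycles).
#'
#' @param occupancy a \code{\link{compute_membership}} result.
#' @param inputs an \code{econ_inputs} object.
#' @param grid a \code{\link{cycle_grid}}.
#' @param arm \code{"intervention"} (atezolizumab + chemotherapy) or
#'   \code{"control"} (chemotherapy).
#' @param ae_once apply adverse-event costs once at cycle 1.
#' @return named list of discounted category totals (US$) plus
#'   \code{total}; attribute \code{"per_cycle"} holds the trace matrix.
#' @export
expected_costs <- function(occupancy, inputs, grid,
                           arm = c("intervention", "control"),
                           ae_once = TRUE) {
  arm <- match.arg(arm)
  n <- grid$n_cycles
  stopifnot(nrow(occupancy) == n)
  pf <- occupancy$pf; pp <- occupancy$pp; dead <- occupancy$dead
  disc <- grid$discount
  v <- function(nm) econ_value(inputs, nm)
  cons <- inputs$constants

  inc_death <- diff(c(0, dead))
  inc_prog <- pmax(diff(-c(1, pf)), 0)   # decline in PF membership
  if (any(inc_death < -1e-9))
    stop("negative incident deaths: OS curve not monotone")

  chemo <- regimen_cycle_cost("carboplatin_etoposide", inputs)[["total"]]
  atezo <- regimen_cycle_cost("atezolizumab", inputs)[["total"]]
  admin <- c(v("cost_admin_first"), rep(v("cost_admin_additional"), n - 1))
  on_chemo <- seq_len(n) <= cons$regimens$chemo_cycles

  drug <- if (arm == "intervention")
    (atezo + chemo * on_chemo) * pf else (chemo * on_chemo) * pf
  admin_cost <- if (arm == "intervention") admin * pf
                else admin * pf * on_chemo
  supportive <- v("cost_supportive_care") * (pf + pp)

  sl <- cons$second_line
  upt <- sl$uptake[[arm]]
  lump <- sl$n_cycles *
    (upt[["topotecan"]] * regimen_cycle_cost("topotecan", inputs)[["total"]] +
     upt[["cav"]] * regimen_cycle_cost("cav", inputs)[["total"]])
  second_line <- lump * inc_prog
  death_cost <- v("cost_death") * pmax(inc_death, 0)

  risk_pref <- if (arm == "intervention") "risk_ac_" else "risk_c_"
  ae_total <- sum(vapply(cons$ae_events, function(e)
    v(paste0(risk_pref, e)) * v(paste0("cost_ae_", e)), 0))
  ae <- numeric(n)
  if (ae_once) ae[1] <- ae_total
  else ae[on_chemo] <- ae_total * pf[on_chemo] / sum(pf[on_chemo])

  mat <- cbind(drug = drug, administration = admin_cost,
               supportive = supportive, second_line = second_line,
               death = death_cost, ae = ae) * disc
  out <- as.list(colSums(mat))
  out$total <- sum(unlist(out))
  attr(out, "per_cycle") <- mat
  out
}

#' Expected discounted QALYs and life-years
#'
#' QALYs accrue per cycle as \eqn{d_k (u_{PF} pf_k + u_{PP} pp_k)
#' \times 21/365.25}, minus a one-time adverse-event decrement
#' \eqn{\sum_{AE} risk \times |disutility| \times duration/365.25} at
#' cycle 1; life-years as \eqn{d_k (pf_k + pp_k) \times 21/365.25}.
#'
#' @inheritParams expected_costs
#' @return list with \code{qaly}, \code{lyg}, \code{ae_decrement}.
#' @export
expected_qalys_lys <- function(occupancy, inputs, grid,
                               arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  n <- grid$n_cycles
  stopifnot(nrow(occupancy) == n)
  v <- function(nm) econ_value(inputs, nm)
  u_pf <- v("utility_pf"); u_pp <- v("utility_pp")
  if (u_pf < 0 || u_pf > 1 || u_pp < 0 || u_pp > 1)
    stop("utilities must lie in [0, 1]")
  cyc_yr <- grid$cycle_length_days / 365.25
  disc <- grid$discount
  qaly_cycles <- sum(disc * (u_pf * occupancy$pf + u_pp * occupancy$pp)) * cyc_yr
  lyg <- sum(disc * (occupancy$pf + occupancy$pp)) * cyc_yr
  risk_pref <- if (arm == "intervention") "risk_ac_" else "risk_c_"
  ae_dec <- sum(vapply(inputs$constants$ae_events, function(e)
    v(paste0(risk_pref, e)) * abs(v(paste0("disutility_", e))) *
      v(paste0("duration_", e)) / 365.25, 0))
  list(qaly = qaly_cycles - ae_dec, lyg = lyg, ae_decrement = ae_dec)
}

#' Run the partitioned survival model for one arm
#'
#' Evaluates the OS and PFS curves on the cycle grid, builds the state
#' occupancy and accumulates discounted costs, QALYs and life-years.
#'
#' @param S_os,S_pfs survival functions of time in months (or vectors on
#'   the grid).
#' @param inputs an \code{econ_inputs}.
#' @param grid a \code{\link{cycle_grid}} (rebuilt from the inputs'
#'   discount rate if it differs).
#' @param arm \code{"intervention"} or \code{"control"}.
#' @param ae_once see \code{\link{expected_costs}}.
#' @return object of class \code{"ps_model"}: list with \code{arm},
#'   \code{occupancy}, \code{costs}, \code{outcomes}, \code{trace} (per
#'   cycle: occupancy, discounted cost categories, discounted QALY
#'   increment).
#' @export
ps_model <- function(S_os, S_pfs, inputs = default_econ_inputs(),
                     grid = NULL, arm = c("intervention", "control"),
                     ae_once = TRUE) {
  arm <- match.arg(arm)
  r <- econ_value(inputs, "discount_rate")
  if (is.null(grid) || abs(grid$discount_rate_annual - r) > 1e-12)
    grid <- cycle_grid(discount_rate_annual = r,
                       half_cycle = if (is.null(grid)) FALSE
                                    else grid$half_cycle)
  occ <- compute_membership(S_os, S_pfs, grid)
  costs <- expected_costs(occ, inputs, grid, arm, ae_once = ae_once)
  outc <- expected_qalys_lys(occ, inputs, grid, arm)
  v <- function(nm) econ_value(inputs, nm)
  trace <- cbind(occ, attr(costs, "per_cycle"),
                 qaly_inc = grid$discount *
                   (v("utility_pf") * occ$pf + v("utility_pp") * occ$pp) *
                   grid$cycle_length_days / 365.25)
  structure(list(arm = arm, grid = grid, occupancy = occ,
                 costs = costs, outcomes = outc, trace = trace),
            class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat("Partitioned survival model --", x$arm, "arm\n")
  cat("  total cost: US$", format(round(x$costs$total), big.mark = ","),
      "  QALYs:", round(x$outcomes$qaly, 3),
      "  LYs:", round(x$outcomes$lyg, 3), "\n")
  cat("  dead at horizon:",
      sprintf("%.1f%%", 100 * x$occupancy$dead[x$grid$n_cycles]), "\n")
  invisible(x)
}

#' @export
summary.ps_model <- function(object, ...) {
  cat("Arm:", object$arm, "\n")
  cat("Cost by category (discounted US$):\n")
  cc <- object$costs; cc <- cc[names(cc) != "total"]
  print(round(unlist(cc), 2))
  cat("Total:", round(object$costs$total, 2), "\n")
  cat("QALYs:", round(object$outcomes$qaly, 4),
      "(AE decrement", round(object$outcomes$ae_decrement, 5), ")",
      " LYs:", round(object$outcomes$lyg, 4), "\n")
  invisible(object)
}

#' @export
plot.ps_model <- function(x, ...) {
  occ <- x$occupancy
  graphics::matplot(occ$time_days / 30.4375,
                    cbind(occ$pf, occ$pp, occ$dead), type = "l",
                    lty = 1, col = c(3, 4, 1),
                    xlab = "Months", ylab = "Proportion", ...)
  graphics::legend("right", c("PF", "PP", "Dead"), col = c(3, 4, 1), lty = 1)
  invisible(x)
}
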