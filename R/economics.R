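#' Incremental cost-effectiveness analysis
#'
#' Computes incremental cost, QALYs and life-years of the intervention vs
#' control arm, the incremental cost-utility ratio (ICUR = \eqn{\Delta
#' C/\Delta QALY}) and cost-effectiveness ratio (ICER = \eqn{\Delta
#' C/\Delta LY}) from unrounded totals. Dominance (cheaper and more
#' effective, or the reverse) and an undefined ratio (\eqn{\Delta QALY =
#' 0}) are flagged instead of reporting a ratio.
#'
#' @param intervention,control \code{\link{ps_model}} results (or any
#'   lists with \code{costs$total} and \code{outcomes$qaly},
#'   \code{outcomes$lyg}).
#' @return object of class \code{"ce_result"}: per-arm totals,
#'   \code{delta_cost}, \code{delta_qaly}, \code{delta_lyg}, \code{icur},
#'   \code{icer}, \code{dominance} (one of \code{"none"},
#'   \code{"dominant"}, \code{"dominated"}), \code{ratio_defined}.
#' @examples
#' a <- list(costs = list(total = 600), outcomes = list(qaly = 1.5, lyg = 2))
#' b <- list(costs = list(total = 500), outcomes = list(qaly = 1.0, lyg = 1.5))
#' incremental_analysis(a, b)$icur  # 200
#' @export
incremental_analysis <- function(intervention, control) {
  dc <- intervention$costs$total - control$costs$total
  dq <- intervention$outcomes$qaly - control$outcomes$qaly
  dl <- intervention$outcomes$lyg - control$outcomes$lyg
  dominance <- if (dc < 0 && dq > 0) "dominant"
               else if (dc > 0 && dq < 0) "dominated" else "none"
  ratio_defined <- abs(dq) > 0 && dominance == "none"
  structure(list(
    arms = data.frame(
      arm = c("intervention", "control"),
      cost = c(intervention$costs$total, control$costs$total),
      qaly = c(intervention$outcomes$qaly, control$outcomes$qaly),
      lyg = c(intervention$outcomes$lyg, control$outcomes$lyg)
    ),
    delta_cost = dc, delta_qaly = dq, delta_lyg = dl,
    icur = if (ratio_defined) dc / dq else NA_real_,
    icer = if (abs(dl) > 0 && dominance == "none") dc / dl else NA_real_,
    dominance = dominance, ratio_defined = ratio_defined
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  df <- x$arms
  df$cost <- round(df$cost); df$qaly <- round(df$qaly, 3)
  df$lyg <- round(df$lyg, 3)
  print(df, row.names = FALSE)
  cat("Incremental: cost US$", format(round(x$delta_cost), big.mark = ","),
      ", QALY", round(x$delta_qaly, 4), ", LY", round(x$delta_lyg, 4), "\n")
  if (x$dominance != "none") cat("Intervention is", x$dominance, "\n")
  else if (!x$ratio_defined) cat("ICUR undefined (zero QALY difference)\n")
  else cat("ICUR: US$", format(round(x$icur), big.mark = ","),
           "/QALY   ICER: US$", format(round(x$icer), big.mark = ","),
           "/LY\n")
  invisible(x)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the model with each input at its low and then high bound,
#' all other inputs at base values, and reports the ICUR at both ends.
#' Inputs without bounds are varied by +/-20\% of the base value. Rows are
#' sorted by bar width, the tornado convention.
#'
#' @param runner function(\code{econ_inputs}) returning a
#'   \code{ce_result} -- typically a closure over fixed survival curves
#'   (see \code{\link{run_pipeline}}).
#' @param inputs base \code{econ_inputs}.
#' @param param_names inputs to vary (default: all with
#'   \code{dist != "fixed"} plus any with distinct bounds).
#' @return data frame of class \code{"tornado"}: \code{name, low, high,
#'   icur_low, icur_high, width}, sorted by decreasing \code{width};
#'   attribute \code{"base_icur"}.
#' @export
one_way_dsa <- function(runner, inputs = default_econ_inputs(),
                        param_names = NULL) {
  pr <- inputs$params
  if (is.null(param_names))
    param_names <- pr$name[pr$dist != "fixed" | pr$low < pr$high]
  base <- runner(inputs)
  rows <- lapply(param_names, function(nm) {
    i <- match(nm, pr$name)
    if (is.na(i)) stop("unknown input '", nm, "'")
    lo <- pr$low[i]; hi <- pr$high[i]
    if (!is.finite(lo) || !is.finite(hi)) {
      lo <- pr$value[i] * 0.8; hi <- pr$value[i] * 1.2
      if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    }
    if (lo > hi) stop("low > high for '", nm, "'")
    r_lo <- runner(econ_override(inputs, stats::setNames(lo, nm)))
    r_hi <- runner(econ_override(inputs, stats::setNames(hi, nm)))
    data.frame(name = nm, low = lo, high = hi,
               icur_low = r_lo$icur, icur_high = r_hi$icur)
  })
  out <- do.call(rbind, rows)
  out$width <- abs(out$icur_high - out$icur_low)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_icur") <- base$icur
  class(out) <- c("tornado", "data.frame")
  out
}

#' Sample one probabilistic draw of the inputs
#'
#' Distributions follow the input ledger: beta for utilities, risks and
#' disutilities (fitted on the magnitude and negated for disutilities),
#' gamma for costs, normal for durations, fixed inputs constant.
#' Parameters come from method of moments with the mean at the
#' deterministic value and SE = (high - low)/3.92, i.e. the bounds read as
#' a 95\% interval. If a beta cannot match the moments (SE too large) the
#' draw falls back to uniform between low and high.
#'
#' @param inputs an \code{econ_inputs}.
#' @param n_draws number of parameter-vector draws.
#' @return matrix (\code{n_draws} x inputs) of sampled values.
#' @keywords internal
sample_psa_inputs <- function(inputs, n_draws) {
  pr <- inputs$params
  out <- matrix(NA_real_, n_draws, nrow(pr),
                dimnames = list(NULL, pr$name))
  for (i in seq_len(nrow(pr))) {
    m <- pr$value[i]; se <- (pr$high[i] - pr$low[i]) / 3.92
    d <- pr$dist[i]
    out[, i] <-
      if (d == "fixed" || se <= 0) rep(m, n_draws)
      else if (d == "gamma") {
        stats::rgamma(n_draws, shape = (m / se)^2, rate = m / se^2)
      } else if (d == "normal") {
        stats::rnorm(n_draws, m, se)
      } else if (d == "beta") {
        sgn <- if (m < 0) -1 else 1
        mu <- abs(m)
        if (mu <= 0 || mu >= 1 || se^2 >= mu * (1 - mu)) {
          sgn * stats::runif(n_draws, min(abs(pr$low[i]), abs(pr$high[i])),
                             max(abs(pr$low[i]), abs(pr$high[i])))
        } else {
          nu <- mu * (1 - mu) / se^2 - 1
          sgn * stats::rbeta(n_draws, mu * nu, (1 - mu) * nu)
        }
      } else stop("unknown distribution '", d, "'")
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws \code{n_draws} joint input vectors from the ledger distributions
#' (draws shared between arms) and re-runs the full model for each,
#' recording incremental cost and QALYs. Reproducible for a fixed seed.
#'
#' @param runner function(\code{econ_inputs}) returning a
#'   \code{ce_result}.
#' @param inputs base \code{econ_inputs}.
#' @param n_draws number of Monte Carlo simulations.
#' @param seed integer seed.
#' @return object of class \code{"ps_psa"}: list with \code{draws} (data
#'   frame \code{draw, delta_cost, delta_qaly, delta_lyg}),
#'   \code{samples} (input matrix), \code{n_draws}, \code{seed}.
#' @export
psa <- function(runner, inputs = default_econ_inputs(), n_draws = 1000,
                seed = 1) {
  set.seed(as.integer(seed))
  samples <- sample_psa_inputs(inputs, n_draws)
  res <- vapply(seq_len(n_draws), function(j) {
    inp_j <- inputs
    inp_j$params$value <- as.numeric(samples[j, ])
    r <- runner(inp_j)
    c(r$delta_cost, r$delta_qaly, r$delta_lyg)
  }, numeric(3))
  structure(list(
    draws = data.frame(draw = seq_len(n_draws),
                       delta_cost = res[1, ], delta_qaly = res[2, ],
                       delta_lyg = res[3, ]),
    samples = samples, n_draws = n_draws, seed = seed
  ), class = "ps_psa")
}

#' @export
print.ps_psa <- function(x, ...) {
  cat("PSA:", x$n_draws, "Monte Carlo draws (seed", x$seed, ")\n")
  cat("  mean incremental cost US$",
      format(round(mean(x$draws$delta_cost)), big.mark = ","),
      "; mean incremental QALY", round(mean(x$draws$delta_qaly), 4), "\n")
  p100k <- mean(1e5 * x$draws$delta_qaly - x$draws$delta_cost > 0)
  cat("  P(cost-effective at US$100,000/QALY):", round(100 * p100k, 1),
      "%\n")
  invisible(x)
}

#' Net monetary benefit of PSA draws
#'
#' \eqn{NMB(\lambda) = \lambda \Delta QALY - \Delta C} per draw.
#'
#' @param x a \code{ps_psa}.
#' @param lambda willingness-to-pay per QALY.
#' @return numeric vector, one value per draw.
#' @export
nmb <- function(x, lambda) {
  lambda * x$draws$delta_qaly - x$draws$delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with positive net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param x a \code{ps_psa} (or data frame with \code{delta_cost},
#'   \code{delta_qaly}).
#' @param lambda willingness-to-pay grid (US$/QALY).
#' @return data frame of class \code{"ceac"}: \code{lambda, p_ce}.
#' @export
ceac <- function(x, lambda = seq(0, 3e5, by = 1e4)) {
  draws <- if (inherits(x, "ps_psa")) x$draws else x
  if (!nrow(draws)) stop("no PSA draws")
  p <- vapply(lambda, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), 0)
  out <- data.frame(lambda = lambda, p_ce = p)
  class(out) <- c("ceac", "data.frame")
  out
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$lambda / 1000, x$p_ce, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (US$1,000/QALY)",
                 ylab = "Probability cost-effective", ...)
  invisible(x)
}

#' @export
plot.ps_psa <- function(x, type = c("ceac", "plane"), ...) {
  type <- match.arg(type)
  if (type == "ceac") return(plot(ceac(x), ...))
  graphics::plot(x$draws$delta_qaly, x$draws$delta_cost,
                 xlab = "Incremental QALYs", ylab = "Incremental cost (US$)",
                 pch = 16, cex = 0.4, col = grDevices::grey(0.4), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Scenario analysis
#'
#' Re-runs the model with named input overrides (e.g. alternative
#' health-state utilities) and reports the scenario result next to the
#' base case for each extrapolation variant supplied.
#'
#' @param runners named list of functions(\code{econ_inputs}) returning
#'   \code{ce_result} objects -- one per extrapolation variant (e.g.
#'   mixture cure vs standard parametric for the intervention arm).
#' @param overrides named numeric vector of input replacements; unknown
#'   names raise an error.
#' @param inputs base \code{econ_inputs}.
#' @return data frame: \code{variant, case, icur, delta_cost,
#'   delta_qaly}.
#' @export
scenario_analysis <- function(runners, overrides,
                              inputs = default_econ_inputs()) {
  scen_inputs <- econ_override(inputs, overrides)
  out <- lapply(names(runners), function(v) {
    base <- runners[[v]](inputs)
    scen <- runners[[v]](scen_inputs)
    data.frame(variant = v, case = c("base", "scenario"),
               icur = c(base$icur, scen$icur),
               delta_cost = c(base$delta_cost, scen$delta_cost),
               delta_qaly = c(base$delta_qaly, scen$delta_qaly))
  })
  do.call(rbind, out)
}
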