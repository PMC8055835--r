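#' Apply background mortality to a fitted survival curve
#'
#' Combines a disease-specific survival model with general-population
#' mortality additively on the hazard scale:
#' \eqn{h_{tot}(t) = h_{model}(t) + h_{gen}(t)}, equivalently
#' \eqn{S_{adj}(t) = S_{model}(t)\,S_{gen}(t)}, with \eqn{S_{gen}} built
#' from annual life-table probabilities converted to hazards. Used for the
#' standard parametric extrapolations; the mixture cure model instead
#' carries the background inside its own likelihood (see
#' \code{\link{fit_mixture_cure}}), whose population survival already
#' includes it.
#'
#' @param fit a \code{psm_parfit}, a \code{psm_curefit} (returned
#'   unchanged apart from wrapping, since its survival already includes
#'   the background), or a plain survival function of time (months).
#' @param lifetable life table data frame, or a ready
#'   \code{background_survival}.
#' @param start_age model entry age (ignored when a
#'   \code{background_survival} is given).
#' @param horizon_months horizon the adjusted curve must cover; an error
#'   is raised if the life table runs out before then.
#' @return an object of class \code{"adjusted_survival"}: list with
#'   \code{S(t)} and \code{h(t)} (per month).
#' @export
apply_background_mortality <- function(fit, lifetable, start_age = 64,
                                       horizon_months = 30) {
  bg <- if (inherits(lifetable, "background_survival")) lifetable
        else lifetable_survival(lifetable, start_age)
  if (bg$max_months < horizon_months)
    stop("life table does not cover the model horizon")
  if (inherits(fit, "psm_curefit")) {
    Sm <- function(t) predict(fit, t) / pmax(bg$S(t), 1e-300)
    hm <- NULL
  } else if (inherits(fit, "psm_parfit")) {
    Sm <- function(t) predict(fit, t, type = "survival")
    hm <- function(t) predict(fit, t, type = "hazard")
  } else if (is.function(fit)) {
    Sm <- fit; hm <- NULL
  } else stop("unsupported 'fit'")
  structure(list(
    S = function(t) Sm(t) * bg$S(t),
    h = if (is.null(hm)) NULL else function(t) hm(t) + bg$h(t),
    background = bg
  ), class = "adjusted_survival")
}

#' @export
print.adjusted_survival <- function(x, ...) {
  cat("Survival curve with additive background mortality (start age",
      x$background$start_age, ")\n")
  invisible(x)
}

#' Proportional-hazards diagnostic for a two-arm dataset
#'
#' Fits a two-arm Cox model and tests the proportional-hazards assumption
#' with the scaled Schoenfeld residual trend test
#' (\code{\link[survival]{cox.zph}}); also returns log cumulative hazard
#' (\eqn{\log(-\log S)}) curves per arm for visual assessment. The p-value
#' is reported against the conventional 0.05 threshold but no decision is
#' enforced.
#'
#' @param data survival dataset with both arms.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @return object of class \code{"ph_test"}: list with \code{hr} (hazard
#'   ratio, second arm level vs first), \code{loghr_se}, \code{statistic}
#'   and \code{p_value} of the Schoenfeld test, \code{reject} (p < 0.05),
#'   and \code{loglog} (data frame \code{arm, time, loglog}).
#' @export
test_ph <- function(data, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  cols <- paste0(tolower(endpoint), c("_time", "_event"))
  arms <- unique(data$arm)
  if (length(arms) != 2) stop("exactly two arms required")
  for (a in arms)
    if (sum(data[data$arm == a, cols[2]]) == 0)
      stop("arm '", a, "' has no events")
  df <- data.frame(time = data[[cols[1]]], event = data[[cols[2]]],
                   arm = factor(data$arm, levels = arms))
  cx <- survival::coxph(survival::Surv(time, event) ~ arm, data = df)
  zp <- survival::cox.zph(cx, transform = "km")
  loglog <- do.call(rbind, lapply(arms, function(a) {
    km <- kaplan_meier(data, endpoint, a)
    st <- km$steps[km$steps$survival > 0 & km$steps$survival < 1, ]
    if (!nrow(st)) return(NULL)
    data.frame(arm = a, time = st$time, loglog = log(-log(st$survival)))
  }))
  structure(list(
    hr = unname(exp(stats::coef(cx))),
    loghr_se = unname(sqrt(diag(cx$var))),
    statistic = zp$table["arm", "chisq"],
    p_value = zp$table["arm", "p"],
    reject = zp$table["arm", "p"] < 0.05,
    loglog = loglog
  ), class = "ph_test")
}

#' @export
print.ph_test <- function(x, ...) {
  cat("Two-arm Cox HR:", signif(x$hr, 4), "\n")
  cat("Schoenfeld PH test: chisq =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 4),
      if (x$reject) "(PH assumption questionable at 0.05)" else "", "\n")
  invisible(x)
}
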