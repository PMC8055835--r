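#' Kaplan-Meier estimation for one arm and endpoint
#'
#' Product-limit estimate with Greenwood standard errors, computed via
#' \code{\link[survival]{survfit}}. The median is the first time at which
#' the estimated survival drops to 0.5 or below; if survival never reaches
#' 0.5 the median is undefined and returned as \code{NA} with
#' \code{median_defined = FALSE}.
#'
#' @param data a survival dataset (see \code{\link{generate_ipd}}), or any
#'   data frame with \code{arm} plus \code{<endpoint>_time} /
#'   \code{<endpoint>_event} columns.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @param arm arm label; NULL allowed when the data contain a single arm.
#' @return object of class \code{"km_curve"}: list with \code{steps} (data
#'   frame \code{time, survival, std_err, n_risk, n_event, n_censor}),
#'   \code{median}, \code{median_defined}, \code{endpoint}, \code{arm},
#'   \code{n}, and the per-patient \code{data} used.
#' @examples
#' d <- data.frame(patient_id = 1:3, arm = "A", os_time = 1:3,
#'                 os_event = 1, pfs_time = 1:3, pfs_event = 1)
#' kaplan_meier(d, "OS", "A")$steps$survival  # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(data, endpoint = c("OS", "PFS"), arm = NULL) {
  endpoint <- match.arg(endpoint)
  if (all(c("time", "event") %in% names(data))) {
    # single-endpoint (e.g. reconstructed) data
    sub <- if (!is.null(arm) && "arm" %in% names(data))
      data[data$arm == arm, , drop = FALSE] else data
    if (!nrow(sub)) stop("no records in arm '", arm, "'")
    if (is.null(arm)) arm <- if ("arm" %in% names(sub)) unique(sub$arm)[1] else ""
    time <- sub$time; event <- sub$event
  } else {
    cols <- paste0(tolower(endpoint), c("_time", "_event"))
    if (!all(cols %in% names(data)))
      stop("data lack columns ", paste(cols, collapse = ", "))
    if (is.null(arm)) {
      if (length(unique(data$arm)) > 1) stop("specify 'arm' for multi-arm data")
      arm <- unique(data$arm)
    }
    sub <- data[data$arm == arm, , drop = FALSE]
    if (!nrow(sub)) stop("no records in arm '", arm, "'")
    time <- sub[[cols[1]]]; event <- sub[[cols[2]]]
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  steps <- data.frame(
    time = fit$time, survival = fit$surv, std_err = fit$surv * fit$std.err,
    n_risk = fit$n.risk, n_event = fit$n.event, n_censor = fit$n.censor
  )
  med <- km_quantile(steps, 0.5)
  structure(list(
    steps = steps, median = med, median_defined = !is.na(med),
    endpoint = endpoint, arm = arm, n = nrow(sub),
    data = data.frame(time = time, event = event)
  ), class = "km_curve")
}

# first time at which survival <= q
km_quantile <- function(steps, q = 0.5) {
  idx <- which(steps$survival <= q + 1e-12)
  if (!length(idx)) return(NA_real_)
  steps$time[min(idx)]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$endpoint, "in arm", x$arm,
      "(n =", paste0(x$n, ")"), "\n")
  cat("  events:", sum(x$steps$n_event), " median:",
      if (x$median_defined) paste(round(x$median, 2), "months")
      else "not reached", "\n")
  invisible(x)
}

#' @export
summary.km_curve <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$steps)
  sf <- stats::stepfun(object$steps$time, c(1, object$steps$survival))
  data.frame(time = times, survival = sf(times))
}

#' @export
plot.km_curve <- function(x, add = FALSE, xlab = "Months",
                          ylab = "Survival", ...) {
  tt <- c(0, x$steps$time); ss <- c(1, x$steps$survival)
  if (add) graphics::lines(tt, ss, type = "s", ...)
  else graphics::plot(tt, ss, type = "s", ylim = c(0, 1),
                      xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
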