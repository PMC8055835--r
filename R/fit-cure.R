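#' Fit a mixture cure model with background mortality
#'
#' Maximum-likelihood fit of the mixture cure model
#' \deqn{S_{pop}(t) = S_{gen}(t)\,\{p_{cured} + (1 - p_{cured})\,
#'   S_{uncured}(t)\}}
#' where \eqn{S_{gen}} is general-population (background) survival from a
#' life table and \eqn{S_{uncured}} one of the standard parametric
#' families. The density used for events is the exact negative derivative
#' of this expression,
#' \deqn{f_{pop}(t) = h_{gen}(t) S_{pop}(t) + S_{gen}(t)(1 - p_{cured})
#'   f_{uncured}(t),}
#' so cured patients die at general-population rates inside the
#' likelihood. Optimization is over \eqn{logit(p_{cured})} and the
#' uncured family's working parameters, multistart over several cure
#' fraction starting values.
#'
#' @inheritParams fit_parametric
#' @param background a \code{\link{lifetable_survival}} object (general
#'   population survival from the model entry age).
#' @param family uncured-kernel family name.
#' @param p_starts cure-fraction starting values for the multistart.
#' @return an object of class \code{"psm_curefit"}: \code{p_cured},
#'   \code{uncured} (named natural parameters), \code{family},
#'   \code{background}, \code{loglik}, \code{aic}
#'   (\eqn{k = } uncured parameters + 1), \code{converged},
#'   \code{boundary} (TRUE when the cure fraction ran to 0 or 1).
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{logLik},
#'   \code{predict} (population/uncured/background survival),
#'   \code{plot}.
#' @export
fit_mixture_cure <- function(time, event = NULL, family = "gompertz",
                             background, data = NULL, restricted = FALSE,
                             p_starts = c(0.05, 0.1, 0.2, 0.35, 0.5)) {
  if (inherits(time, "formula")) {
    mf <- stats::model.frame(time, data = data)
    y <- stats::model.response(mf)
    event <- y[, "status"]; time <- y[, "time"]
  }
  stopifnot(length(time) == length(event))
  if (!inherits(background, "background_survival"))
    stop("'background' must come from lifetable_survival()")
  if (any(time / 12 > (background$max_months / 12)))
    stop("background survival not defined over the whole follow-up")
  fam <- surv_family(family, restricted = restricted)
  if (sum(event) < fam$npar + 2)
    stop("too few events for a cure fit")
  Sg <- background$S(time); hg <- background$h(time)

  negll <- function(x) {
    ll <- suppressWarnings({
      p <- stats::plogis(x[1])
      th <- fam$to_natural(x[-1])
      Su <- fam$S(time, th); fu <- fam$f(time, th)
      Spop <- Sg * (p + (1 - p) * Su)
      fpop <- hg * Spop + Sg * (1 - p) * fu
      sum(event * log(pmax(fpop, 1e-300)) +
            (1 - event) * log(pmax(Spop, 1e-300)))
    })
    if (!is.finite(ll)) 1e10 else -ll
  }
  x0_fam <- fam$to_working(fam$start(time, event))
  best <- NULL
  for (p0 in p_starts) {
    opt <- try(stats::optim(c(stats::qlogis(p0), x0_fam), negll,
                            method = "BFGS",
                            control = list(maxit = 1000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("cure-model optimization failed")
  p_cured <- stats::plogis(best$par[1])
  uncured <- fam$to_natural(best$par[-1])
  boundary <- p_cured < 1e-3 || p_cured > 1 - 1e-3
  if (boundary)
    warning("cure fraction at boundary (", signif(p_cured, 3), ")")
  k <- fam$npar + 1
  structure(list(
    p_cured = p_cured, uncured = uncured, family = fam,
    background = background, working = best$par,
    loglik = -best$value, aic = 2 * best$value + 2 * k, k = k,
    converged = best$convergence == 0, boundary = boundary,
    n = length(time), n_event = sum(event),
    data = data.frame(time = time, event = event)
  ), class = "psm_curefit")
}

#' @export
print.psm_curefit <- function(x, ...) {
  cat("Mixture cure fit (uncured kernel:", x$family$name,
      if (isTRUE(x$family$restricted)) "restricted" else "", ")\n")
  cat("  cure fraction:", signif(x$p_cured, 4),
      if (x$boundary) "[boundary]" else "", "\n  uncured: ")
  cat(paste(names(x$uncured), signif(x$uncured, 5), sep = " = ",
            collapse = ", "), "\n")
  cat("logLik:", format(x$loglik, digits = 6), "  AIC:",
      format(x$aic, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' @export
summary.psm_curefit <- function(object, ...) {
  cat("Mixture cure model, n =", object$n, ", events =", object$n_event, "\n")
  print(object)
  invisible(object)
}

#' @export
coef.psm_curefit <- function(object, ...) {
  c(p_cured = object$p_cured, object$uncured)
}

#' @export
logLik.psm_curefit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' Predict survival from a mixture cure fit
#'
#' @param object a \code{psm_curefit}.
#' @param times evaluation times (months).
#' @param type \code{"survival"} (population, including background),
#'   \code{"uncured"} (uncured kernel alone), or \code{"background"}.
#' @param ... unused.
#' @export
predict.psm_curefit <- function(object, times,
                                type = c("survival", "uncured",
                                         "background"), ...) {
  type <- match.arg(type)
  Su <- object$family$S(times, object$uncured)
  switch(type,
    survival = object$background$S(times) *
      (object$p_cured + (1 - object$p_cured) * Su),
    uncured = Su,
    background = object$background$S(times)
  )
}

#' @export
plot.psm_curefit <- function(x, max_time = NULL, ...) {
  km <- kaplan_meier(data.frame(time = x$data$time, event = x$data$event))
  if (is.null(max_time)) max_time <- max(x$data$time) * 1.25
  plot(km, main = "KM vs mixture cure fit", ...)
  tt <- seq(0, max_time, length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  graphics::abline(h = x$p_cured, lty = 3)
  invisible(x)
}
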