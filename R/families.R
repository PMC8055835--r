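#' Parametric survival families
#'
#' The five standard parametric families used for survival extrapolation,
#' with fixed, documented parameterizations:
#'
#' \describe{
#'   \item{exponential}{\code{rate} \eqn{\lambda > 0}; \eqn{S(t) = e^{-\lambda t}},
#'     \eqn{h(t) = \lambda}.}
#'   \item{weibull}{\code{shape} \eqn{k > 0}, \code{scale} \eqn{\sigma > 0};
#'     \eqn{S(t) = e^{-(t/\sigma)^k}}, \eqn{h(t) = (k/\sigma)(t/\sigma)^{k-1}}
#'     (the \code{\link[stats]{pweibull}} parameterization).}
#'   \item{gompertz}{\code{shape} \eqn{a \in R}, \code{rate} \eqn{b > 0};
#'     \eqn{h(t) = b e^{a t}}, \eqn{S(t) = \exp\{-b(e^{at}-1)/a\}}
#'     (\eqn{S(t) = e^{-bt}} at \eqn{a = 0}). With \eqn{a < 0} the hazard
#'     decays and a survival plateau \eqn{S(\infty) = e^{b/a}} appears; the
#'     \emph{restricted} variant constrains \eqn{a \ge 0} so that everyone
#'     eventually fails.}
#'   \item{loglogistic}{\code{shape} \eqn{k > 0}, \code{scale} \eqn{\sigma > 0};
#'     \eqn{S(t) = 1/(1 + (t/\sigma)^k)}.}
#'   \item{lognormal}{\code{meanlog} \eqn{\mu}, \code{sdlog} \eqn{\sigma > 0};
#'     \eqn{S(t) = 1 - \Phi((\log t - \mu)/\sigma)}.}
#' }
#'
#' \code{surv_family()} returns the family descriptor: closed forms for the
#' survival, density and hazard functions, a random generator, the
#' transformation between natural and unconstrained optimizer scales, and a
#' moment-style starting-value heuristic.
#'
#' @param name one of \code{"exponential"}, \code{"weibull"},
#'   \code{"gompertz"}, \code{"loglogistic"}, \code{"lognormal"}.
#' @param restricted for \code{"gompertz"} only: constrain the shape to be
#'   non-negative (monotone non-decreasing hazard).
#' @return an object of class \code{"surv_family"}: a list with elements
#'   \code{name}, \code{pnames}, \code{npar}, and functions \code{S(t, p)},
#'   \code{f(t, p)}, \code{h(t, p)}, \code{r(n, p)}, \code{to_natural(x)},
#'   \code{to_working(p)}, \code{start(time, event)}.
#' @examples
#' fam <- surv_family("gompertz")
#' fam$S(12, c(shape = 0.1, rate = 0.05))
#' @export
surv_family <- function(name = c("exponential", "weibull", "gompertz",
                                 "loglogistic", "lognormal"),
                        restricted = FALSE) {
  name <- match.arg(name)
  fam <- switch(name,
    exponential = fam_exponential(),
    weibull     = fam_weibull(),
    gompertz    = fam_gompertz(restricted),
    loglogistic = fam_loglogistic(),
    lognormal   = fam_lognormal()
  )
  fam$name <- name
  fam$npar <- length(fam$pnames)
  class(fam) <- "surv_family"
  fam
}

#' @export
print.surv_family <- function(x, ...) {
  cat("Parametric survival family:", x$name,
      if (isTRUE(x$restricted)) "(restricted)" else "", "\n")
  cat("  parameters:", paste(x$pnames, collapse = ", "), "\n")
  invisible(x)
}

fam_exponential <- function() {
  list(
    pnames = "rate",
    S = function(t, p) exp(-p[[1]] * t),
    f = function(t, p) p[[1]] * exp(-p[[1]] * t),
    h = function(t, p) rep_len(p[[1]], length(t)),
    r = function(n, p) stats::rexp(n, rate = p[[1]]),
    to_natural = function(x) c(rate = exp(x[[1]])),
    to_working = function(p) log(p[[1]]),
    start = function(time, event) {
      c(rate = max(sum(event), 0.5) / sum(time))
    }
  )
}

fam_weibull <- function() {
  list(
    pnames = c("shape", "scale"),
    S = function(t, p) exp(-(t / p[[2]])^p[[1]]),
    f = function(t, p) stats::dweibull(t, shape = p[[1]], scale = p[[2]]),
    h = function(t, p) (p[[1]] / p[[2]]) * (t / p[[2]])^(p[[1]] - 1),
    r = function(n, p) stats::rweibull(n, shape = p[[1]], scale = p[[2]]),
    to_natural = function(x) c(shape = exp(x[[1]]), scale = exp(x[[2]])),
    to_working = function(p) log(c(p[[1]], p[[2]])),
    start = function(time, event) {
      tt <- time[event == 1]
      if (length(tt) < 2) tt <- time
      # crude shape from log-time spread; exact value irrelevant (multistart)
      shp <- min(max(1.2 / stats::sd(log(pmax(tt, 1e-8))), 0.2), 10)
      c(shape = shp, scale = stats::median(tt) / log(2)^(1 / shp))
    }
  )
}

fam_gompertz <- function(restricted = FALSE) {
  H <- function(t, a, b) {
    if (abs(a) < 1e-10) b * t else b * expm1(a * t) / a
  }
  out <- list(
    pnames = c("shape", "rate"),
    restricted = restricted,
    S = function(t, p) exp(-H(t, p[[1]], p[[2]])),
    f = function(t, p) p[[2]] * exp(p[[1]] * t) * exp(-H(t, p[[1]], p[[2]])),
    h = function(t, p) p[[2]] * exp(p[[1]] * t),
    r = function(n, p) {
      a <- p[[1]]; b <- p[[2]]
      u <- stats::runif(n)
      if (abs(a) < 1e-10) return(-log(u) / b)
      arg <- 1 - a * log(u) / b
      # a < 0 leaves mass at +Inf (defective distribution)
      out <- rep(Inf, n)
      out[arg > 0] <- log(arg[arg > 0]) / a
      out
    },
    start = function(time, event) {
      rate <- max(sum(event), 0.5) / sum(time)
      c(shape = 0.05, rate = rate)
    }
  )
  if (restricted) {
    out$to_natural <- function(x) c(shape = exp(x[[1]]), rate = exp(x[[2]]))
    out$to_working <- function(p) log(c(max(p[[1]], 1e-8), p[[2]]))
  } else {
    out$to_natural <- function(x) c(shape = x[[1]], rate = exp(x[[2]]))
    out$to_working <- function(p) c(p[[1]], log(p[[2]]))
  }
  out
}

fam_loglogistic <- function() {
  list(
    pnames = c("shape", "scale"),
    S = function(t, p) 1 / (1 + (t / p[[2]])^p[[1]]),
    f = function(t, p) {
      k <- p[[1]]; s <- p[[2]]
      z <- (t / s)^k
      (k / s) * (t / s)^(k - 1) / (1 + z)^2
    },
    h = function(t, p) {
      k <- p[[1]]; s <- p[[2]]
      (k / s) * (t / s)^(k - 1) / (1 + (t / s)^k)
    },
    r = function(n, p) {
      u <- stats::runif(n)
      p[[2]] * (u / (1 - u))^(-1 / p[[1]])
    },
    to_natural = function(x) c(shape = exp(x[[1]]), scale = exp(x[[2]])),
    to_working = function(p) log(c(p[[1]], p[[2]])),
    start = function(time, event) {
      tt <- time[event == 1]
      if (length(tt) < 2) tt <- time
      c(shape = min(max(1.8 / stats::sd(log(pmax(tt, 1e-8))), 0.2), 10),
        scale = stats::median(tt))
    }
  )
}

fam_lognormal <- function() {
  list(
    pnames = c("meanlog", "sdlog"),
    S = function(t, p) stats::plnorm(t, p[[1]], p[[2]], lower.tail = FALSE),
    f = function(t, p) stats::dlnorm(t, p[[1]], p[[2]]),
    h = function(t, p) {
      stats::dlnorm(t, p[[1]], p[[2]]) /
        pmax(stats::plnorm(t, p[[1]], p[[2]], lower.tail = FALSE), 1e-300)
    },
    r = function(n, p) stats::rlnorm(n, p[[1]], p[[2]]),
    to_natural = function(x) c(meanlog = x[[1]], sdlog = exp(x[[2]])),
    to_working = function(p) c(p[[1]], log(p[[2]])),
    start = function(time, event) {
      tt <- time[event == 1]
      if (length(tt) < 2) tt <- time
      c(meanlog = mean(log(pmax(tt, 1e-8))),
        sdlog = max(stats::sd(log(pmax(tt, 1e-8))), 0.2))
    }
  )
}

#' Survival under the non-mixture (proportional hazards) cure formulation
#'
#' Evaluates \eqn{S_{pop}(t) = S_{gen}(t)\,\exp\{\ln(p_{cured})(1 - S(t))\}},
#' where \eqn{S} is a standard extrapolation distribution decreasing to zero.
#' The cumulative excess hazard asymptotes to \eqn{-\ln p_{cured}}, so
#' \eqn{S_{pop}/S_{gen} \to p_{cured}}. Provided for evaluation and
#' comparison only; no fitting routine is attached because the formulation
#' presumes proportional hazards between arms, which survival data with a
#' cure plateau typically violate.
#'
#' @param p_cured cured fraction, in (0, 1]; \code{p_cured = 0} is an error
#'   (the log is undefined).
#' @param S survival value(s) of the standard distribution at \code{t}, or a
#'   function of time.
#' @param t time(s); only needed when \code{S} (or \code{S_gen}) is a function.
#' @param S_gen background general-population survival at \code{t} (value(s)
#'   or function); defaults to 1 (no background mortality).
#' @return survival probabilities, same length as the input.
#' @examples
#' survival_non_mixture_cure(0.5, S = 0.5)  # exp(log(0.5) * 0.5) ~ 0.7071
#' @export
survival_non_mixture_cure <- function(p_cured, S, t = NULL, S_gen = 1) {
  if (length(p_cured) != 1 || is.na(p_cured) || p_cured <= 0 || p_cured > 1)
    stop("'p_cured' must be a single value in (0, 1]; the log of 0 is undefined")
  if (is.function(S)) S <- S(t)
  if (is.function(S_gen)) S_gen <- S_gen(t)
  if (any(S < 0 | S > 1)) stop("'S' must lie in [0, 1]")
  S_gen * exp(log(p_cured) * (1 - S))
}
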