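#' Life tables and background survival
#'
#' A life table is a data frame with columns \code{age} (years, strictly
#' increasing) and \code{qx} (annual probability of death, in [0,1]).
#' \code{lifetable_survival()} converts it, from a given starting age, into
#' a background survival function on the month time scale by turning each
#' annual probability into a constant hazard over that year of age
#' (\eqn{h = -\log(1 - q_x)} per year).
#'
#' @param lifetable data frame with columns \code{age}, \code{qx}.
#' @param start_age age (years) at model entry; must be covered by the table.
#' @return an object of class \code{"background_survival"}: list with
#'   \code{S(t)}, \code{h(t)} (hazard per month), \code{H(t)} (cumulative
#'   hazard), \code{r(n)} (random residual-life draws in months, \code{Inf}
#'   beyond table coverage), \code{start_age}, and \code{max_months} of
#'   coverage.
#' @examples
#' lt <- data.frame(age = 60:100, qx = pmin(0.01 * 1.09^(0:40), 0.7))
#' bg <- lifetable_survival(lt, start_age = 64)
#' bg$S(12)
#' @export
lifetable_survival <- function(lifetable, start_age) {
  validate_lifetable(lifetable)
  if (start_age < min(lifetable$age))
    stop("start_age below life-table coverage")
  lt <- lifetable[lifetable$age >= floor(start_age), , drop = FALSE]
  if (nrow(lt) < 1) stop("start_age beyond life-table coverage")
  haz_yr <- -log(pmax(1 - lt$qx, 1e-12))        # per-year hazard by age row
  # assume each row's qx applies for one year of age
  knots_m <- (lt$age - start_age) * 12
  knots_m[1] <- max(knots_m[1], 0)
  ends_m <- c(knots_m[-1], (max(lt$age) + 1 - start_age) * 12)
  widths <- (ends_m - knots_m) / 12              # years within each band
  Hcum <- c(0, cumsum(haz_yr * widths))          # at band boundaries
  max_m <- ends_m[length(ends_m)]
  Hfun <- function(t) {
    t <- pmin(pmax(t, 0), max_m)
    i <- findInterval(t, knots_m, rightmost.closed = FALSE)
    i <- pmax(i, 1L)
    Hcum[i] + haz_yr[i] * (t - knots_m[i]) / 12
  }
  hfun <- function(t) {
    i <- pmax(findInterval(pmin(pmax(t, 0), max_m - 1e-9), knots_m), 1L)
    haz_yr[i] / 12                               # per month
  }
  rfun <- function(n) {
    u <- stats::runif(n)
    target <- -log(u)
    Hmax <- Hcum[length(Hcum)]
    out <- rep(Inf, n)
    idx <- target < Hmax
    if (any(idx)) {
      band <- findInterval(target[idx], Hcum, rightmost.closed = FALSE)
      band <- pmin(pmax(band, 1L), length(haz_yr))
      out[idx] <- knots_m[band] +
        12 * (target[idx] - Hcum[band]) / haz_yr[band]
    }
    out
  }
  structure(
    list(S = function(t) exp(-Hfun(t)), H = Hfun, h = hfun, r = rfun,
         start_age = start_age, max_months = max_m),
    class = "background_survival"
  )
}

#' @export
print.background_survival <- function(x, ...) {
  cat("Background survival from life table; start age", x$start_age,
      "years,", round(x$max_months / 12), "years of coverage\n")
  invisible(x)
}

validate_lifetable <- function(lifetable) {
  if (!is.data.frame(lifetable) || !all(c("age", "qx") %in% names(lifetable)))
    stop("life table must be a data frame with columns 'age' and 'qx'")
  if (any(diff(lifetable$age) <= 0)) stop("life-table ages must be strictly increasing")
  if (any(lifetable$qx < 0 | lifetable$qx > 1)) stop("qx must lie in [0, 1]")
  invisible(lifetable)
}

#' Simplified general-population life table
#'
#' A synthetic all-cause annual mortality table for ages 40-100 built from a
#' Gompertz-Makeham law, \eqn{\mu(a) = A + B e^{Ca}} with \eqn{A = 5\times
#' 10^{-4}}, \eqn{B = 4.5\times 10^{-5}}, \eqn{C = 0.085}, chosen to sit
#' close to recent US sex-averaged adult mortality (about 1.1\% at age 64,
#' 2.5\% at 74). It stands in for an official age- and sex-adjusted table,
#' which cannot be redistributed here; any table with the same two columns
#' can be supplied instead wherever a life table is accepted.
#'
#' @param ages integer vector of ages (years).
#' @return data frame with columns \code{age}, \code{qx}.
#' @examples
#' lt <- default_lifetable()
#' lt[lt$age == 64, ]
#' @export
default_lifetable <- function(ages = 40:100) {
  mu <- 5e-4 + 4.5e-5 * exp(0.085 * ages)
  data.frame(age = ages, qx = pmin(1 - exp(-mu), 0.99))
}

#' Write / read the life-table CSV dialect
#'
#' Plain CSV with header \code{age,qx}.
#' @param lifetable data frame with columns \code{age}, \code{qx}.
#' @param path file path.
#' @return \code{read_lifetable} returns the validated data frame.
#' @export
write_lifetable <- function(lifetable, path) {
  validate_lifetable(lifetable)
  utils::write.csv(lifetable[, c("age", "qx")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_lifetable
#' @export
read_lifetable <- function(path) {
  validate_lifetable(utils::read.csv(path))
}
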