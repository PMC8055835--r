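#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' Interval-wise iterative reconstruction in the Guyot style. Within each
#' interval between published numbers-at-risk, the algorithm walks the
#' digitized survival steps keeping a running product-limit estimate; at
#' every observed drop it chooses the event count together with the number
#' of censorings leaving the risk set just before the drop so that the
#' reconstructed step ratio matches the digitized one as closely as the
#' integer risk set allows, spending a censoring budget that is iterated
#' until the implied number at risk at the next interval boundary matches
#' the published one. Censoring times are placed inside flat segments of
#' the curve (a censoring leaves no survival step), falling back to even
#' spacing. Re-running \code{\link{kaplan_meier}} on the output reproduces
#' the input coordinates -- exactly when there is no censoring, and within
#' a small tolerance otherwise.
#'
#' Digitization noise is tolerated: survival values are clamped to [0, 1]
#' and monotonized by cumulative minimum before reconstruction, with a
#' warning. At tied times events are processed before censorings (the
#' standard KM convention). A coordinate lying exactly on a risk-table
#' boundary is assigned to the earlier interval, matching the convention
#' that numbers at risk are counted just before the boundary.
#'
#' If no risk table is supplied, a single interval covering the whole
#' curve is used with no interior censoring unless \code{total_events} is
#' given (coordinates-only mode; flagged in the output attributes).
#'
#' @param coords data frame with columns \code{time}, \code{survival}
#'   (one arm, one endpoint), coordinates monotone non-increasing.
#' @param risk_table data frame with columns \code{time}, \code{n_risk}
#'   (aligned to interval boundaries; first row gives the initial n), or
#'   NULL for coordinates-only mode.
#' @param n_start initial number at risk; required when \code{risk_table}
#'   is NULL, otherwise taken from its first row.
#' @param total_events optional published total event count; when
#'   supplied, the reconstruction is adjusted at the tail so the total
#'   matches.
#' @return data frame with columns \code{time}, \code{event} (0/1), one
#'   row per reconstructed patient; attribute \code{"mode"} records
#'   whether a risk table was used.
#' @examples
#' d <- data.frame(patient_id = 1:3, arm = "A", os_time = 1:3, os_event = 1,
#'                 pfs_time = 1:3, pfs_event = 1)
#' dig <- digitize_km(d, grid = 1:3, risk_times = 0:3, endpoints = "OS")
#' rec <- reconstruct_ipd(dig$km_points[c("time", "survival")],
#'                        dig$risk_table[c("time", "n_risk")])
#' table(rec$event)
#' @export
reconstruct_ipd <- function(coords, risk_table = NULL, n_start = NULL,
                            total_events = NULL) {
  if (!all(c("time", "survival") %in% names(coords)))
    stop("coords need columns 'time' and 'survival'")
  coords <- coords[order(coords$time), , drop = FALSE]
  s <- coords$survival
  if (any(s < -1e-9 | s > 1 + 1e-9) || any(diff(s) > 1e-9)) {
    warning("survival coordinates clamped to [0,1] and monotonized")
  }
  s <- cummin(pmin(pmax(s, 0), 1))
  tt <- coords$time
  keep <- !duplicated(tt)
  tt <- tt[keep]; s <- s[keep]
  if (length(tt) && tt[1] <= 0) { s <- s[tt > 0]; tt <- tt[tt > 0] }

  mode <- "risk_table"
  if (is.null(risk_table)) {
    mode <- "coords_only"
    if (is.null(n_start)) stop("'n_start' required without a risk table")
    risk_table <- data.frame(time = 0, n_risk = n_start)
  }
  risk_table <- risk_table[order(risk_table$time), , drop = FALSE]
  if (any(risk_table$n_risk > risk_table$n_risk[1]))
    stop("risk counts exceed the initial number at risk")
  n0 <- risk_table$n_risk[1]
  if (!length(tt)) {
    out <- data.frame(time = numeric(), event = integer())
    attr(out, "mode") <- mode
    return(out)
  }

  # interval boundaries; a coordinate at a boundary belongs to the earlier
  # interval
  bounds <- c(risk_table$time, max(tt))
  bounds <- bounds[!duplicated(bounds)]
  if (length(bounds) > 1 && bounds[length(bounds)] <= bounds[length(bounds) - 1])
    bounds <- bounds[-length(bounds)]
  nint <- length(bounds) - 1
  if (nint == 0) { bounds <- c(bounds, max(tt) + 1); nint <- 1 }

  # one allocation pass through an interval: choose, at each digitized
  # drop, the event count and preceding censor count that best match the
  # step ratio given the integer risk set, under a censoring budget C
  alloc_pass <- function(r0, S0, kk, C) {
    r <- r0; Sloc <- S0; Crem <- C
    nk <- length(kk)
    d <- integer(nk); cb <- integer(nk)
    for (j in seq_len(nk)) {
      q <- if (Sloc > 0) s[kk[j]] / Sloc else 1
      if (q >= 1 - 1e-12 || r <= 0) next     # flat coordinate: no events
      best_err <- Inf; best_c <- 0L; best_d <- 0L
      for (cc in 0:Crem) {
        rr <- r - cc
        if (rr <= 0) break
        dd <- max(0L, min(as.integer(round(rr * (1 - q))), rr))
        err <- abs((1 - dd / rr) - q) + 1e-5 * cc
        if (err < best_err - 1e-15) { best_err <- err; best_c <- cc; best_d <- dd }
        if (best_err < 1e-12) break
      }
      cb[j] <- best_c; d[j] <- best_d
      rr <- r - best_c
      if (best_d > 0) Sloc <- Sloc * (1 - best_d / rr)
      r <- rr - best_d
      Crem <- Crem - best_c
    }
    list(d = d, cb = cb, leftover = Crem, r = r, S = Sloc)
  }

  ev_time <- numeric(0); cen_time <- numeric(0)
  n_cur <- n0
  S_run <- 1
  for (i in seq_len(nint)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    kk <- which(tt > lo + 1e-12 & tt <= hi + 1e-12)
    if (i == 1) kk <- which(tt <= hi + 1e-12)
    if (i == nint) kk <- which(tt > if (i == 1) -Inf else lo + 1e-12)
    n_next <- if (i + 1 <= nrow(risk_table)) risk_table$n_risk[i + 1] else NA
    cguess <- 0L
    pass <- alloc_pass(n_cur, S_run, kk, cguess)
    if (!is.na(n_next)) {
      for (iter in 1:40) {
        cnew <- max(0L, n_cur - n_next - sum(pass$d))
        if (cnew == cguess) break
        cguess <- cnew
        pass <- alloc_pass(n_cur, S_run, kk, cguess)
      }
    }
    # materialize times: events at their coordinates, censors just before
    # the drop they precede (inside the preceding flat stretch)
    prev_t <- lo
    for (j in seq_along(kk)) {
      tk <- tt[kk[j]]
      if (pass$cb[j] > 0) {
        gap_lo <- max(prev_t, lo)
        pos <- gap_lo + seq_len(pass$cb[j]) * (tk - gap_lo) / (pass$cb[j] + 1)
        cen_time <- c(cen_time, pos)
      }
      if (pass$d[j] > 0) ev_time <- c(ev_time, rep(tk, pass$d[j]))
      if (pass$d[j] > 0 || pass$cb[j] > 0) prev_t <- tk
    }
    used_cen <- sum(pass$cb)
    leftover <- if (is.na(n_next)) 0L else
      max(0L, n_cur - n_next - sum(pass$d) - used_cen)
    if (leftover > 0) {
      gap_lo <- max(prev_t, lo)
      pos <- gap_lo + seq_len(leftover) * (hi - gap_lo) / (leftover + 1)
      cen_time <- c(cen_time, pos)
    }
    n_cur <- n_cur - sum(pass$d) - used_cen - leftover
    S_run <- pass$S
    if (n_cur <= 0) { n_cur <- 0; break }
  }
  # patients still at risk after the last coordinate: administratively
  # censored there
  if (n_cur > 0) cen_time <- c(cen_time, rep(max(tt), n_cur))

  if (!is.null(total_events)) {
    diff_ev <- total_events - length(ev_time)
    if (diff_ev > 0 && length(cen_time)) {
      take <- order(cen_time, decreasing = TRUE)[
        seq_len(min(diff_ev, length(cen_time)))]
      ev_time <- c(ev_time, rep(max(tt), length(take)))
      cen_time <- cen_time[-take]
    } else if (diff_ev < 0 && length(ev_time)) {
      take <- order(ev_time, decreasing = TRUE)[
        seq_len(min(-diff_ev, length(ev_time)))]
      cen_time <- c(cen_time, ev_time[take])
      ev_time <- ev_time[-take]
    }
  }
  out <- data.frame(
    time = c(ev_time, cen_time),
    event = c(rep(1L, length(ev_time)), rep(0L, length(cen_time)))
  )
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Reconstruct a full trial dataset from digitized curves
#'
#' Applies \code{\link{reconstruct_ipd}} to every (arm, endpoint)
#' combination of a digitized-curve pack (the format produced by
#' \code{\link{digitize_km}}) and returns one long data frame.
#'
#' @param km_points data frame \code{arm, endpoint, time, survival}.
#' @param risk_table data frame \code{arm, endpoint, time, n_risk}.
#' @return data frame \code{arm, endpoint, time, event}.
#' @export
reconstruct_trial <- function(km_points, risk_table) {
  combos <- unique(km_points[c("arm", "endpoint")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    a <- combos$arm[i]; ep <- combos$endpoint[i]
    co <- km_points[km_points$arm == a & km_points$endpoint == ep,
                    c("time", "survival")]
    rt <- risk_table[risk_table$arm == a & risk_table$endpoint == ep,
                     c("time", "n_risk")]
    rec <- reconstruct_ipd(co, if (nrow(rt)) rt else NULL,
                           n_start = if (nrow(rt)) NULL else NA)
    if (nrow(rec)) data.frame(arm = a, endpoint = ep, rec) else NULL
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
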