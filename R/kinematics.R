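# Kinematic preprocessing of four-limb motion-capture series: instantaneous
# 3D speed by central differences, the 1-min sliding-window displacement
# rate, its baseline-normalised ratio, and 2-min block summaries.

#' Construct a position series
#'
#' A uniformly sampled 3D marker trajectory. Timestamps are seconds from
#' recording start; coordinates are millimetres.
#'
#' Missing samples (`NA`, e.g. dropped markers) are filled by linear
#' interpolation when the gap is at most `max_gap` seconds; longer gaps or
#' missing endpoints reject the series, mirroring the exclusion policy for
#' tracking failures.
#'
#' @param t Numeric vector of timestamps (s), uniformly spaced.
#' @param x,y,z Coordinates (mm), same length as `t`.
#' @param rate_hz Sampling rate; defaults to the reciprocal median spacing.
#' @param max_gap Longest interpolatable gap in seconds (default 0.5).
#' @return A `position_series` data frame with columns `t`, `x`, `y`, `z`.
#' @export
position_series <- function(t, x, y, z, rate_hz = NULL, max_gap = 0.5) {
  n <- length(t)
  if (n < 3)
    mk_error("position series needs at least 3 samples",
             "mobilekin_insufficient_data")
  if (length(x) != n || length(y) != n || length(z) != n)
    mk_error("coordinate lengths differ from timestamps",
             "mobilekin_invalid_spec")
  dt <- diff(t)
  if (any(!is.finite(dt)) || any(abs(dt - dt[1]) > 1e-6))
    mk_error("timestamps must be uniformly spaced",
             "mobilekin_invalid_spec")
  if (is.null(rate_hz)) rate_hz <- 1 / median(dt)
  gap <- is.na(x) | is.na(y) | is.na(z)
  if (any(gap)) {
    if (gap[1] || gap[n])
      mk_error("series starts or ends with missing samples",
               "mobilekin_gap_error")
    runs <- rle(gap)
    if (max(runs$lengths[runs$values]) / rate_hz > max_gap)
      mk_error(sprintf("marker gap longer than %.2f s; session rejected",
                       max_gap), "mobilekin_gap_error")
    x[gap] <- approx(t[!gap], x[!gap], xout = t[gap])$y
    y[gap] <- approx(t[!gap], y[!gap], xout = t[gap])$y
    z[gap] <- approx(t[!gap], z[!gap], xout = t[gap])$y
  }
  out <- data.frame(t = t, x = x, y = y, z = z)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("position_series", "data.frame")
  out
}

#' Instantaneous 3D speed by central differences
#'
#' For interior samples, the speed is
#' \deqn{V_t = \sqrt{\left(\frac{x_{t+1}-x_{t-1}}{2T}\right)^2 +
#'   \left(\frac{y_{t+1}-y_{t-1}}{2T}\right)^2 +
#'   \left(\frac{z_{t+1}-z_{t-1}}{2T}\right)^2}}
#' with sampling period \eqn{T}. The two endpoint samples are dropped.
#'
#' @param p A `position_series`.
#' @return A `speed_series` data frame with columns `t` and `v` (mm/s).
#' @export
instantaneous_speed <- function(p) {
  n <- nrow(p)
  if (n < 3)
    mk_error("need at least 3 samples for central differences",
             "mobilekin_insufficient_data")
  T <- 1 / attr(p, "rate_hz")
  i <- 2:(n - 1)
  dx <- (p$x[i + 1] - p$x[i - 1]) / (2 * T)
  dy <- (p$y[i + 1] - p$y[i - 1]) / (2 * T)
  dz <- (p$z[i + 1] - p$z[i - 1]) / (2 * T)
  out <- data.frame(t = p$t[i], v = sqrt(dx^2 + dy^2 + dz^2))
  attr(out, "rate_hz") <- attr(p, "rate_hz")
  class(out) <- c("speed_series", "data.frame")
  out
}

#' Sliding-window displacement rate
#'
#' Mean of the instantaneous speed over a centred window \eqn{[t-\tau,
#' t+\tau]}; with the default \eqn{\tau = 30} s this is the amount of
#' movement in a 1-min window. Near the recording edges the window is
#' truncated to the available support and the mean taken over the actual
#' samples, so full-session curves are defined from the first sample on.
#'
#' @param v A `speed_series`.
#' @param tau Half-window length in seconds (default 30).
#' @return A `rate_series` data frame with columns `t` (window centres) and
#'   `rate` (mm/s); one row per input sample.
#' @export
displacement_rate <- function(v, tau = 30) {
  if (tau <= 0) mk_error("tau must be positive", "mobilekin_invalid_spec")
  n <- nrow(v)
  span <- v$t[n] - v$t[1]
  if (span < 2 * tau)
    mk_error(sprintf("series spans %.2f s; need at least 2*tau = %.2f s",
                     span, 2 * tau), "mobilekin_insufficient_data")
  rate_hz <- attr(v, "rate_hz")
  half <- floor(tau * rate_hz + 1e-9)
  cs <- c(0, cumsum(v$v))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  sums <- cs[hi + 1L] - cs[lo]
  out <- data.frame(t = v$t, rate = sums / (hi - lo + 1L))
  attr(out, "rate_hz") <- rate_hz
  attr(out, "tau") <- tau
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Baseline ratio of the displacement rate
#'
#' Divides the displacement rate by its baseline-phase mean, so values above
#' one signal more movement than during baseline. The divisor is the mean
#' rate over window centres whose full \eqn{\pm\tau} window lies inside the
#' baseline interval (for a \[0, 120) s baseline and \eqn{\tau = 30} s,
#' centres with \eqn{t \in [30, 90]} s); by construction the mean ratio over
#' those centres equals one.
#'
#' @param r A `rate_series`.
#' @param baseline Length-2 numeric, the baseline interval in seconds
#'   (default `c(0, 120)`).
#' @return A `ratio_series` data frame with columns `t` and `ratio`;
#'   attributes `baseline_mean` (the divisor, mm/s) and `baseline_centres`
#'   (logical index of the divisor-defining rows).
#' @export
baseline_ratio <- function(r, baseline = c(0, 120)) {
  tau <- attr(r, "tau")
  tol <- 1e-9
  centres <- r$t >= baseline[1] + tau - tol & r$t <= baseline[2] - tau + tol
  if (!any(centres))
    mk_error("no window centres with full support inside the baseline",
             "mobilekin_insufficient_data")
  div <- mean(r$rate[centres])
  if (div <= 0)
    mk_error("baseline mean displacement rate is zero (motionless limb)",
             "mobilekin_degenerate_baseline")
  out <- data.frame(t = r$t, ratio = r$rate / div)
  attr(out, "baseline_mean") <- div
  attr(out, "baseline_centres") <- centres
  attr(out, "tau") <- tau
  attr(out, "rate_hz") <- attr(r, "rate_hz")
  class(out) <- c("ratio_series", "data.frame")
  out
}

#' Map anatomical markers to limb roles
#'
#' Given which wrist is tethered to the mobile, markers are relabelled to
#' the four limb roles: connected arm (ConA), unconnected arm (UncA),
#' ipsilateral leg (IpsiL, same side as the connected arm) and contralateral
#' leg (ContL).
#'
#' @param connected_side `"left"` or `"right"` (the connected wrist), or a
#'   session object with a `connected_side` field.
#' @return Named character vector mapping markers `LW`, `RW`, `LA`, `RA` to
#'   roles.
#' @export
relabel_limbs <- function(connected_side) {
  if (is.list(connected_side)) connected_side <- connected_side$connected_side
  side <- match.arg(connected_side, c("left", "right"))
  if (side == "right")
    c(RW = "ConA", LW = "UncA", RA = "IpsiL", LA = "ContL")
  else
    c(LW = "ConA", RW = "UncA", LA = "IpsiL", RA = "ContL")
}

#' Block means of a rate or ratio series
#'
#' Arithmetic mean of the series over window centres falling in each
#' half-open block interval (default: baseline B and play blocks P1..P5 in
#' 2-min steps).
#'
#' @param series A `rate_series` or `ratio_series`.
#' @param blocks Data frame with columns `block`, `start`, `end` (seconds);
#'   defaults to [default_blocks()].
#' @return Data frame with columns `block` and `mean` (one row per block).
#' @export
block_means <- function(series, blocks = default_blocks()) {
  value <- if ("rate" %in% names(series)) series$rate else series$ratio
  out <- vapply(seq_len(nrow(blocks)), function(b) {
    sel <- series$t >= blocks$start[b] & series$t < blocks$end[b]
    if (!any(sel))
      mk_error(sprintf("block %s contains no window centres",
                       blocks$block[b]), "mobilekin_insufficient_data")
    mean(value[sel])
  }, numeric(1))
  data.frame(block = blocks$block, mean = out)
}

#' Down-sample a series to 1 Hz
#'
#' Decimates a rate or ratio series by taking, for each integer second of
#' `t_grid`, the value at the nearest available window centre (exact
#' decimation when a centre falls on the integer second).
#'
#' @param series A `rate_series` or `ratio_series`.
#' @param t_grid Integer seconds to sample at (default `0:719`).
#' @return Data frame with columns `t` and the series' value column.
#' @export
downsample_1hz <- function(series, t_grid = 0:719) {
  col <- if ("rate" %in% names(series)) "rate" else "ratio"
  idx <- findInterval(t_grid, series$t, all.inside = TRUE)
  left <- series$t[idx]
  right <- series$t[pmin(idx + 1L, nrow(series))]
  pick <- ifelse(abs(t_grid - left) <= abs(right - t_grid), idx,
                 pmin(idx + 1L, nrow(series)))
  out <- data.frame(t = t_grid, value = series[[col]][pick])
  names(out)[2] <- col
  out
}
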