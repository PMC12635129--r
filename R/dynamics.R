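# Infant-mobile coupled oscillator model and cluster-level simulation:
# a van der Pol-Duffing limit-cycle oscillator for the limb, a damped
# harmonic oscillator for the mobile, and a slow feedback variable that
# raises the limb's oscillation frequency while the mobile moves.

#' Model parameters for the infant-mobile system
#'
#' The limb obeys \eqn{\ddot x + \dot x(\gamma + \alpha x^2) +
#' x(\omega_0^2 + \delta x^2) = 0}, the mobile \eqn{\ddot y + \varepsilon
#' \dot y + \Omega_0^2 y = c x}, and the feedback \eqn{\dot\delta = a y^2 -
#' \kappa\delta}. With \eqn{\gamma < 0 < \alpha} the limb settles on a limit
#' cycle (spontaneous movement); during play (\eqn{c > 0}) mobile motion
#' feeds back through \eqn{\delta} and speeds the limb up.
#'
#' @param gamma Linear damping of the limb oscillator (negative: self-excited).
#' @param alpha Nonlinear damping coefficient.
#' @param omega0 Natural oscillation frequency of the limb; the single
#'   parameter varied across infants/clusters.
#' @param epsilon Mobile damping.
#' @param Omega0 Mobile eigenfrequency.
#' @param a Feedback gain from mobile motion to limb frequency.
#' @param kappa Decay rate of the feedback variable.
#' @param c_baseline,c_play Infant-to-mobile coupling in the baseline and
#'   play phases.
#' @param dt Integration/reporting step (model time units).
#' @return A `dyn_params` list.
#' @export
dyn_params <- function(gamma = -0.25, alpha = 1, omega0 = 1, epsilon = 1,
                       Omega0 = 2.2, a = 0.13, kappa = 0.007,
                       c_baseline = 0, c_play = 2, dt = 0.01) {
  if (dt <= 0) mk_error("dt must be positive", "mobilekin_invalid_spec")
  structure(list(gamma = gamma, alpha = alpha, omega0 = omega0,
                 epsilon = epsilon, Omega0 = Omega0, a = a, kappa = kappa,
                 c_baseline = c_baseline, c_play = c_play, dt = dt),
            class = "dyn_params")
}

#' Simulate the infant-mobile system
#'
#' Integrates the coupled system with fixed-step fourth-order Runge-Kutta at
#' step `dt`, over a schedule of (duration, coupling) segments; state carries
#' over across segments. One model time unit is treated as one second, so the
#' default schedule is a 120 s baseline (`c = c_baseline`) followed by 600 s
#' of play (`c = c_play`). An initial burn-in segment with baseline coupling
#' is integrated and discarded so the limb starts on its limit cycle.
#'
#' @param params A [dyn_params()] list.
#' @param schedule Data frame with columns `duration` (s) and `c`; default
#'   120 s baseline + 600 s play.
#' @param init Initial state `c(x, xdot, y, ydot, delta)`.
#' @param burn_in Discarded lead-in duration (s) at baseline coupling
#'   (default 60; 0 disables).
#' @return A `dyn_trajectory` data frame with columns `t`, `x`, `xdot`, `y`,
#'   `ydot`, `delta`, reported every `dt`.
#' @export
simulate_mobile <- function(params, schedule = NULL,
                            init = c(x = 1, xdot = 0, y = 0, ydot = 0,
                                     delta = 0),
                            burn_in = 60) {
  if (is.null(schedule))
    schedule <- data.frame(duration = c(120, 600),
                           c = c(params$c_baseline, params$c_play))
  if (any(schedule$duration <= 0))
    mk_error("segment durations must be positive", "mobilekin_invalid_spec")
  state <- as.numeric(init)
  if (burn_in > 0) {
    pre <- .rk4_mobile(state, burn_in, params$c_baseline, params$gamma,
                       params$alpha, params$omega0, params$epsilon,
                       params$Omega0, params$a, params$kappa, params$dt)
    state <- as.numeric(pre[nrow(pre), 2:6])
  }
  m <- .rk4_mobile(state, schedule$duration, schedule$c, params$gamma,
                   params$alpha, params$omega0, params$epsilon,
                   params$Omega0, params$a, params$kappa, params$dt)
  out <- as.data.frame(m)
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  class(out) <- c("dyn_trajectory", "data.frame")
  out
}

#' Simulated learning curve (connected-arm analogue)
#'
#' Converts a model trajectory into the baseline-ratio curve the pipeline
#' computes for a real connected arm: the speed proxy is \eqn{|\dot x(t)|},
#' fed through the same displacement-rate and baseline-ratio operations used
#' for motion-capture data.
#'
#' @param traj A `dyn_trajectory` spanning baseline + play.
#' @param tau Half-window for the displacement rate (s, default 30).
#' @param baseline Baseline interval in seconds (default `c(0, 120)`).
#' @return A `ratio_series` (see [baseline_ratio()]).
#' @export
model_learning_curve <- function(traj, tau = 30, baseline = c(0, 120)) {
  dt <- attr(traj, "params")$dt
  sp <- data.frame(t = traj$t, v = abs(traj$xdot))
  attr(sp, "rate_hz") <- 1 / dt
  class(sp) <- c("speed_series", "data.frame")
  r <- displacement_rate(sp, tau = tau)
  baseline_ratio(r, baseline = baseline)
}

#' Simulate an ensemble of infants for one cluster
#'
#' Draws `n` natural frequencies \eqn{\omega_0} i.i.d. uniformly from
#' `omega0_range`, simulates each infant's session, computes each simulated
#' connected-arm baseline-ratio curve at 1 Hz, and averages them pointwise.
#'
#' @param n Ensemble size (the cluster's infant count).
#' @param omega0_range Length-2 numeric, the uniform range for
#'   \eqn{\omega_0} (default width 0.5).
#' @param params Shared [dyn_params()] (the `omega0` field is overridden
#'   per draw).
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @param t_grid 1 Hz sampling grid for the returned curves.
#' @return List with `mean_curve` (data frame `t`, `ratio`), `curves`
#'   (n x length(t_grid) matrix), `omega0` (the draws) and `failed`
#'   (indices of excluded blow-ups).
#' @export
simulate_cluster <- function(n, omega0_range, params = dyn_params(),
                             seed = 1, t_grid = 0:719) {
  if (n < 1) mk_error("n must be >= 1", "mobilekin_invalid_spec")
  omega0 <- with_seed(seed, runif(n, omega0_range[1], omega0_range[2]))
  curves <- matrix(NA_real_, n, length(t_grid))
  failed <- integer(0)
  for (i in seq_len(n)) {
    p <- params
    p$omega0 <- omega0[i]
    curve <- tryCatch({
      traj <- simulate_mobile(p)
      downsample_1hz(model_learning_curve(traj), t_grid)$ratio
    }, mobilekin_error = function(e) NULL, error = function(e) NULL)
    if (is.null(curve)) failed <- c(failed, i) else curves[i, ] <- curve
  }
  if (length(failed) > n / 10)
    mk_error(sprintf("%d of %d ensemble members failed to integrate",
                     length(failed), n), "mobilekin_integration_failure")
  ok <- setdiff(seq_len(n), failed)
  list(mean_curve = data.frame(t = t_grid,
                               ratio = colMeans(curves[ok, , drop = FALSE])),
       curves = curves[ok, , drop = FALSE],
       omega0 = omega0, failed = failed)
}

#' Mean ratio over the final 2-min play block
#'
#' @param curve Data frame with columns `t` and `ratio` (1 Hz curve).
#' @param block Interval in seconds (default the last play block,
#'   `c(600, 720)`).
#' @return Scalar mean ratio.
#' @export
final_block_mean <- function(curve, block = c(600, 720)) {
  sel <- curve$t >= block[1] & curve$t < block[2]
  mean(curve$ratio[sel])
}

#' Fit the cluster-mean natural frequency by grid search
#'
#' For each candidate mean `m` in `grid`, simulates an ensemble with
#' \eqn{\omega_0 \sim U(m - w/2, m + w/2)} and scores the mean squared
#' deviation of the ensemble-mean ratio curve from `target` over play-phase
#' points. Ties break toward the smaller candidate.
#'
#' @param target Data frame `t`, `ratio`: the cluster-mean curve to match
#'   (1 Hz).
#' @param params Shared [dyn_params()].
#' @param grid Candidate mean \eqn{\omega_0} values.
#' @param n Ensemble size per candidate.
#' @param seed Integer seed (same seed used for every candidate).
#' @param width Width of the uniform range around each candidate
#'   (default 0.5).
#' @return List with `omega0` (best mean), `loss` (named loss profile over
#'   the grid).
#' @export
fit_omega0 <- function(target, params = dyn_params(), grid, n, seed = 1,
                       width = 0.5) {
  if (length(grid) < 1) mk_error("empty grid", "mobilekin_invalid_spec")
  grid <- sort(grid)
  play <- target$t >= 120
  loss <- rep(NA_real_, length(grid))
  for (g in seq_along(grid)) {
    sim <- tryCatch(
      simulate_cluster(n, grid[g] + c(-width, width) / 2, params,
                       seed = seed, t_grid = target$t),
      mobilekin_error = function(e) NULL)
    if (!is.null(sim))
      loss[g] <- mean((sim$mean_curve$ratio[play] - target$ratio[play])^2)
  }
  if (all(is.na(loss)))
    mk_error("all candidates failed integration",
             "mobilekin_fitting_failure")
  best <- which.min(loss)  # first minimum = smallest candidate on ties
  list(omega0 = grid[best], loss = setNames(loss, format(grid)))
}
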