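# Seedable synthetic sessions and cohorts. Each limb's 1-D model coordinate
# is embedded in 3D as rest point + gain * x(t) * unit direction, plus
# isotropic Gaussian jitter; only the speed magnitude matters downstream,
# so the embedding direction is immaterial.

#' Behavioural archetype specification
#'
#' Describes one of the four behavioural clusters the generator can emulate:
#' a natural-frequency range for the limb oscillator, per-limb coupling
#' attenuation during play, a target baseline displacement rate, per-limb
#' gains and measurement noise.
#'
#' @param cluster_id Integer 1-4.
#' @param omega0_range Length-2 numeric; uniform range for \eqn{\omega_0}
#'   (width 0.5 by convention).
#' @param baseline_level Target baseline displacement rate (mm/s), or `NULL`
#'   to use `limb_gain` as the raw model-to-mm scale.
#' @param limb_gain Named per-limb-role multiplicative gain (dimensionless).
#' @param noise_sd Gaussian positional jitter SD (mm) added to every
#'   coordinate.
#' @param c_gain Named per-limb-role attenuation of the play-phase coupling
#'   `c` (connected arm always 1; legs > 0 produce all-limb increases).
#' @return An `archetype_spec` list.
#' @export
archetype_spec <- function(cluster_id, omega0_range, baseline_level = NULL,
                           limb_gain = c(ConA = 1, UncA = 1, IpsiL = 1,
                                         ContL = 1),
                           noise_sd = 0.02,
                           c_gain = c(ConA = 1, UncA = 1, IpsiL = 0,
                                      ContL = 0)) {
  if (noise_sd < 0)
    mk_error("noise_sd must be >= 0", "mobilekin_invalid_spec")
  if (any(limb_gain <= 0))
    mk_error("limb gains must be positive", "mobilekin_invalid_spec")
  if (diff(omega0_range) <= 0)
    mk_error("omega0_range must be increasing", "mobilekin_invalid_spec")
  structure(list(cluster_id = as.integer(cluster_id),
                 omega0_range = omega0_range,
                 baseline_level = baseline_level,
                 limb_gain = limb_gain[LIMB_ROLES],
                 noise_sd = noise_sd,
                 c_gain = c_gain[LIMB_ROLES]),
            class = "archetype_spec")
}

#' Default archetypes for the four behavioural clusters
#'
#' Natural-frequency ranges follow the cluster-wise uniform distributions
#' used in the simulations: (2.8, 3.3) for cluster 1 (no increase),
#' (0.9, 1.4) for cluster 2 (arm increase), (1.4, 1.9) for cluster 3
#' (all-limb increase), and (0.3, 0.8) for cluster 4 (arm more increase).
#' Baseline displacement-rate targets are highest for cluster 1 and lowest
#' for clusters 2 and 4, mirroring the observed baseline-level ordering.
#' Legs couple at half strength in cluster 3 (the all-limb archetype) and
#' are uncoupled elsewhere.
#'
#' @param noise_sd Positional jitter SD in mm (default 0.02, the residual jitter of smoothed marker trajectories).
#' @return List of four [archetype_spec()] objects.
#' @export
default_archetypes <- function(noise_sd = 0.02) {
  ranges <- list(c(2.8, 3.3), c(0.9, 1.4), c(1.4, 1.9), c(0.3, 0.8))
  levels <- c(30, 15, 20, 10)
  leg_c <- c(0, 0, 0.5, 0)
  lapply(1:4, function(i)
    archetype_spec(i, ranges[[i]], baseline_level = levels[i],
                   noise_sd = noise_sd,
                   c_gain = c(ConA = 1, UncA = 1, IpsiL = leg_c[i],
                              ContL = leg_c[i])))
}

#' Cohort specification
#'
#' @param n_per_cluster Four integers; defaults to the study's cluster sizes
#'   (102, 47, 27, 9).
#' @param n_per_age Two integers (2-month, 3-month); defaults to (90, 95).
#' @param seed Master seed from which per-session seeds are derived.
#' @param sampling_rate Motion-capture rate in Hz (default 60).
#' @param phase_durations Baseline and play durations in seconds
#'   (default `c(120, 600)`).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_cluster = c(102, 47, 27, 9),
                        n_per_age = c(90, 95), seed = 1,
                        sampling_rate = 60, phase_durations = c(120, 600)) {
  if (any(n_per_cluster < 0) || any(n_per_age < 0))
    mk_error("counts must be >= 0", "mobilekin_invalid_spec")
  if (sampling_rate <= 0 || any(phase_durations <= 0))
    mk_error("rate and durations must be positive",
             "mobilekin_invalid_spec")
  if (sum(n_per_cluster) != sum(n_per_age))
    mk_error("n_per_cluster and n_per_age totals differ",
             "mobilekin_invalid_spec")
  structure(list(n_per_cluster = n_per_cluster, n_per_age = n_per_age,
                 seed = seed, sampling_rate = sampling_rate,
                 phase_durations = phase_durations),
            class = "cohort_spec")
}

#' Generate one synthetic session
#'
#' Simulates four limb trajectories from the infant-mobile model. The
#' connected arm uses the full play coupling; the other limbs run
#' independent oscillators whose play coupling is attenuated by the
#' archetype's `c_gain` (zero for a limb that keeps moving spontaneously).
#' Each limb draws its own \eqn{\omega_0} from the archetype range. The 1-D
#' model coordinate is interpolated to the motion-capture grid, scaled to
#' millimetres and embedded along a fixed per-limb direction with Gaussian
#' jitter.
#'
#' @param archetype An [archetype_spec()].
#' @param age_group `"2mo"` or `"3mo"`.
#' @param connected_side `"left"` or `"right"`.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param id Session id string.
#' @param rate_hz Sampling rate (Hz, default 60).
#' @param phase_durations Baseline and play durations in seconds.
#' @param params Shared [dyn_params()].
#' @return A `mobile_session` list: `id`, `age_group`, `connected_side`,
#'   `rate_hz`, `phases`, `limbs` (four `position_series` keyed LW/RW/LA/RA)
#'   and `cluster_id` (generating archetype, ground truth).
#' @export
generate_session <- function(archetype, age_group = c("2mo", "3mo"),
                             connected_side = c("right", "left"),
                             seed = 1, id = sprintf("s%06d", seed),
                             rate_hz = 60, phase_durations = c(120, 600),
                             params = dyn_params()) {
  age_group <- match.arg(age_group)
  connected_side <- match.arg(connected_side)
  if (rate_hz <= 0 || any(phase_durations <= 0))
    mk_error("rate and durations must be positive",
             "mobilekin_invalid_spec")
  stopifnot(inherits(archetype, "archetype_spec"))

  total <- sum(phase_durations)
  n <- round(total * rate_hz)
  tg <- (seq_len(n) - 1) / rate_hz
  role_of <- relabel_limbs(connected_side)     # marker -> role
  marker_of <- setNames(names(role_of), role_of)

  # fixed anatomical rest points (mm) and unit embedding directions
  rest <- list(LW = c(-150, 250, 50), RW = c(150, 250, 50),
               LA = c(-100, -250, 40), RA = c(100, -250, 40))
  dirs <- list(LW = c(1, 0, 0), RW = c(1, 0, 0),
               LA = c(0, 1, 0), RA = c(0, 1, 0))

  limbs <- setNames(vector("list", 4), LIMB_MARKERS)
  for (k in seq_along(LIMB_ROLES)) {
    role <- LIMB_ROLES[k]
    marker <- marker_of[[role]]
    limb <- with_seed(derive_seed(seed, k), {
      omega0 <- runif(1, archetype$omega0_range[1],
                      archetype$omega0_range[2])
      p <- params
      p$omega0 <- omega0
      sched <- data.frame(
        duration = phase_durations,
        c = c(p$c_baseline, p$c_play * archetype$c_gain[[role]]))
      traj <- simulate_mobile(p, schedule = sched)
      x <- approx(traj$t, traj$x, xout = tg, rule = 2)$y
      gain <- archetype$limb_gain[[role]]
      if (!is.null(archetype$baseline_level)) {
        base_speed <- mean(abs(traj$xdot[traj$t < phase_durations[1]]))
        gain <- gain * archetype$baseline_level / base_speed
      }
      d <- dirs[[marker]]
      pos <- outer(x * gain, d) +
        matrix(rest[[marker]], n, 3, byrow = TRUE)
      if (archetype$noise_sd > 0)
        pos <- pos + matrix(rnorm(3 * n, sd = archetype$noise_sd), n, 3)
      position_series(tg, pos[, 1], pos[, 2], pos[, 3], rate_hz = rate_hz)
    })
    limbs[[marker]] <- limb
  }

  structure(list(id = id, age_group = age_group,
                 connected_side = connected_side, rate_hz = rate_hz,
                 phases = c(baseline = phase_durations[1],
                            play = phase_durations[2]),
                 limbs = limbs,
                 cluster_id = archetype$cluster_id,
                 seed = seed),
            class = "mobile_session")
}

#' Generate a synthetic cohort
#'
#' Produces `sum(n_per_cluster)` sessions, each tagged with its generating
#' cluster id. Ages and connected sides are assigned deterministically in a
#' counterbalanced round-robin honouring the age totals, and per-session
#' seeds are derived from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @param archetypes List of four [archetype_spec()] objects (default
#'   [default_archetypes()]).
#' @param params Shared [dyn_params()].
#' @return List with `sessions` (list of `mobile_session`) and `manifest`
#'   (data frame: session_id, age_group, connected_side, cluster_id, seed).
#' @export
generate_cohort <- function(spec, archetypes = default_archetypes(),
                            params = dyn_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(archetypes) != 4)
    mk_error("need exactly 4 archetypes", "mobilekin_invalid_spec")
  n_total <- sum(spec$n_per_cluster)
  cluster <- rep(1:4, times = spec$n_per_cluster)
  # counterbalanced deterministic assignment honouring the age totals
  ages <- character(n_total)
  left <- spec$n_per_age
  for (i in seq_len(n_total)) {
    pick <- if (left[1] * spec$n_per_age[2] >= left[2] * spec$n_per_age[1])
      1L else 2L
    if (left[pick] == 0) pick <- 3L - pick
    ages[i] <- c("2mo", "3mo")[pick]
    left[pick] <- left[pick] - 1L
  }
  sides <- rep(c("right", "left"), length.out = n_total)
  seeds <- vapply(seq_len(n_total), function(i)
    derive_seed(spec$seed, 1000 + i), integer(1))
  sessions <- lapply(seq_len(n_total), function(i)
    generate_session(archetypes[[cluster[i]]], age_group = ages[i],
                     connected_side = sides[i], seed = seeds[i],
                     id = sprintf("s%03d", i),
                     rate_hz = spec$sampling_rate,
                     phase_durations = spec$phase_durations,
                     params = params))
  manifest <- data.frame(
    session_id = vapply(sessions, `[[`, "", "id"),
    age_group = ages, connected_side = sides,
    cluster_id = cluster, seed = seeds)
  list(sessions = sessions, manifest = manifest)
}
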