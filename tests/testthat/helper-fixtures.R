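# Shared fixtures, built lazily and cached so expensive simulations run
# once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A zero-noise cluster-4 session plus its kinematic curves.
cluster4_session <- function() fixture("cluster4_session", function() {
  arch <- archetype_spec(4, c(0.3, 0.8), baseline_level = 10, noise_sd = 0)
  s <- generate_session(arch, "2mo", "right", seed = 11)
  list(session = s, curves = session_curves(s))
})

# Narrow, well-separated archetypes used for ground-truth recovery tests.
separated_archetypes <- function(noise_sd = 0) list(
  archetype_spec(1, c(3.0, 3.1), baseline_level = 30, noise_sd = noise_sd),
  archetype_spec(2, c(1.1, 1.2), baseline_level = 15, noise_sd = noise_sd),
  archetype_spec(3, c(1.6, 1.7), baseline_level = 20, noise_sd = noise_sd,
                 c_gain = c(ConA = 1, UncA = 1, IpsiL = 0.5, ContL = 0.5)),
  archetype_spec(4, c(0.5, 0.6), baseline_level = 10, noise_sd = noise_sd))

# A long-format table with no true effects (null simulation input).
null_long_table <- function(n_per_group = 30, p = 6) {
  n <- 2 * n_per_group
  long_table(subject = rep(seq_len(n), each = p),
             between = rep(c("g1", "g2"), each = p * n_per_group),
             within = rep(paste0("w", seq_len(p)), n),
             value = rnorm(n * p))
}

# Build a speed_series directly from values (uniform sampling).
make_speed <- function(v, rate_hz = 1, t0 = 0) {
  out <- data.frame(t = t0 + (seq_along(v) - 1) / rate_hz, v = v)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("speed_series", "data.frame")
  out
}

# Build a rate_series directly from values.
make_rate <- function(rate, rate_hz = 1, t0 = 0, tau = 30) {
  out <- data.frame(t = t0 + (seq_along(rate) - 1) / rate_hz, rate = rate)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "tau") <- tau
  class(out) <- c("rate_series", "data.frame")
  out
}

# Exhaustive K-means oracle: global minimum of the objective over all k^n
# assignments (centres at member means); infeasible beyond tiny n.
exhaustive_kmeans_D <- function(F, k) {
  n <- nrow(F)
  stopifnot(n <= 8)
  best <- Inf
  idx <- rep(1L, n)
  repeat {
    D <- 0
    for (i in seq_len(k)) {
      m <- idx == i
      if (any(m)) {
        centre <- colMeans(F[m, , drop = FALSE])
        D <- D + sum(sweep(F[m, , drop = FALSE], 2, centre)^2)
      }
    }
    if (D < best) best <- D
    j <- 1L
    while (j <= n && idx[j] == k) { idx[j] <- 1L; j <- j + 1L }
    if (j > n) break
    idx[j] <- idx[j] + 1L
  }
  best
}

# Synthetic two-archetype feature rows (flat ~1 vs play-phase rise to ~3).
two_group_features <- function(n_each = 3, T = 60, seed = 4) {
  withr::with_seed(seed, {
    t <- seq_len(T)
    flat <- t(replicate(n_each, 1 + rnorm(T, sd = 0.05)))
    rise <- t(replicate(n_each, ifelse(t > T / 3, 3, 1) + rnorm(T, sd = 0.05)))
    rbind(flat, rise)
  })
}
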