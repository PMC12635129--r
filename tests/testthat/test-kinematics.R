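test_that("central-difference speed is exact on constant and linear motion", {
  t <- (0:299) / 60
  p0 <- position_series(t, rep(5, 300), rep(-2, 300), rep(1, 300))
  expect_equal(instantaneous_speed(p0)$v, rep(0, 298))

  # straight-line motion at (3, 4, 0) mm/s: speed 5 everywhere (3-4-5)
  p1 <- position_series(t, 3 * t, 4 * t, rep(0, 300))
  sp <- instantaneous_speed(p1)
  expect_equal(sp$v, rep(5, 298), tolerance = 1e-12)
  expect_equal(sp$t, t[2:299])
  expect_equal(nrow(sp), 298)

  expect_error(instantaneous_speed(position_series(0:2, 1:3, 1:3, 1:3)[1:2, ]),
               class = "mobilekin_insufficient_data")
})

test_that("central-difference speed matches the closed form on circular motion", {
  # radius 10 mm, angular rate pi rad/s at 60 Hz; the discrete central
  # difference of a sinusoid has magnitude r*omega*sinc(omega*T)
  r <- 10; omega <- pi; rate <- 60; T <- 1 / rate
  t <- (0:599) * T
  p <- position_series(t, r * cos(omega * t), r * sin(omega * t),
                       rep(0, 600))
  v <- instantaneous_speed(p)$v
  discrete <- r * omega * sin(omega * T) / (omega * T)
  expect_equal(v, rep(discrete, 598), tolerance = 1e-10)
  # and the continuum speed r*omega to second-order accuracy (< 0.05%)
  expect_lt(max(abs(v - r * omega)) / (r * omega), 5e-4)
})

test_that("displacement rate is a truncated-window mean of the speed", {
  # constant speed: rate constant everywhere, including truncated edges
  v <- make_speed(rep(2.5, 721), rate_hz = 1)
  r <- displacement_rate(v, tau = 30)
  expect_equal(r$rate, rep(2.5, 721))

  # step speed 1 -> 3 at t = 60: full window at t = 60 averages to 2
  # (up to the one-sample asymmetry of the inclusive discrete window)
  v2 <- make_speed(c(rep(1, 60 * 60), rep(3, 60 * 60)), rate_hz = 60)
  r2 <- displacement_rate(v2, tau = 30)
  i <- seq(1, nrow(v2), by = 37)
  oracle <- vapply(i, function(j) {
    w <- abs(v2$t - v2$t[j]) <= 30 + 1e-9
    mean(v2$v[w])
  }, numeric(1))
  expect_equal(r2$rate[i], oracle, tolerance = 1e-12)
  expect_equal(r2$rate[r2$t == 60], 2, tolerance = 1e-3)

  # tau = 30 gives a 1-min interior window
  v3 <- make_speed(rnorm(721)^2, rate_hz = 1)
  r3 <- displacement_rate(v3, tau = 30)
  interior <- 400
  w <- abs(v3$t - v3$t[interior]) <= 30 + 1e-9
  expect_equal(diff(range(v3$t[w])), 60)

  expect_error(displacement_rate(make_speed(rep(1, 50), rate_hz = 1), 30),
               class = "mobilekin_insufficient_data")
})

test_that("sliding-window rate equals a naive per-sample oracle", {
  withr::with_seed(42, {
    for (rate_hz in c(1, 10)) {
      n <- 1500
      v <- make_speed(abs(rnorm(n)), rate_hz = rate_hz)
      tau <- 25
      r <- displacement_rate(v, tau = tau)
      oracle <- vapply(seq_len(n), function(i) {
        w <- abs(v$t - v$t[i]) <= tau + 1e-9
        mean(v$v[w])
      }, numeric(1))
      expect_equal(r$rate, oracle, tolerance = 1e-12)
    }
  })
})

test_that("baseline ratio averages to one over the divisor-defining centres", {
  withr::with_seed(3, {
    v <- make_speed(abs(rnorm(721)) + 0.1, rate_hz = 1)
    r <- displacement_rate(v, tau = 30)
    q <- baseline_ratio(r, baseline = c(0, 120))
    centres <- attr(q, "baseline_centres")
    expect_equal(range(r$t[centres]), c(30, 90))
    expect_equal(mean(q$ratio[centres]), 1, tolerance = 1e-12)
  })
})

test_that("baseline ratio is scale invariant and degenerate baselines error", {
  # an ideal doubling step in the rate maps to a late ratio of 2
  r <- make_rate(c(rep(4, 360), rep(8, 361)), rate_hz = 1)
  q <- baseline_ratio(r)
  expect_equal(q$ratio[q$t == 700], 2)
  expect_equal(attr(q, "baseline_mean"), 4)

  r0 <- make_rate(c(rep(0, 200), rep(1, 521)), rate_hz = 1)
  expect_error(baseline_ratio(r0), class = "mobilekin_degenerate_baseline")
})

test_that("scaling positions scales speed and rate but not the ratio", {
  withr::with_seed(9, {
    t <- (0:7199) / 10
    wiggle <- function() cumsum(rnorm(7200, sd = 0.5))
    x <- wiggle(); y <- wiggle(); z <- wiggle()
    lambda <- 3.7
    chain <- function(scale) {
      p <- position_series(t, scale * x, scale * y, scale * z)
      r <- displacement_rate(instantaneous_speed(p), tau = 30)
      list(rate = r, ratio = baseline_ratio(r))
    }
    a <- chain(1); b <- chain(lambda)
    expect_equal(b$rate$rate, lambda * a$rate$rate, tolerance = 1e-12)
    expect_equal(b$ratio$ratio, a$ratio$ratio, tolerance = 1e-12)
  })
})

test_that("limb roles follow the connected side and mirror correctly", {
  expect_equal(relabel_limbs("right"),
               c(RW = "ConA", LW = "UncA", RA = "IpsiL", LA = "ContL"))
  expect_equal(relabel_limbs("left"),
               c(LW = "ConA", RW = "UncA", LA = "IpsiL", RA = "ContL"))
  # the two mappings are mirror images of each other
  right <- relabel_limbs("right"); left <- relabel_limbs("left")
  mirror <- c(LW = "RW", RW = "LW", LA = "RA", RA = "LA")
  expect_equal(unname(right[mirror[names(left)]]), unname(left))
})

test_that("block means cover six 2-min blocks and match analytic values", {
  r <- make_rate(rep(7, 721), rate_hz = 1)
  bm <- block_means(r)
  expect_equal(bm$block, c("B", "P1", "P2", "P3", "P4", "P5"))
  expect_equal(bm$mean, rep(7, 6))

  # linear ramp 0 -> 1 over the session: block means at interval midpoints
  ramp <- make_rate(seq(0, 1, length.out = 721), rate_hz = 1)
  bm2 <- block_means(ramp)
  mids <- (seq(0, 600, 120) + seq(120, 720, 120)) / 2 / 720
  expect_equal(bm2$mean, mids, tolerance = 2e-3)

  short <- make_rate(rep(1, 100), rate_hz = 1)
  expect_error(block_means(short), class = "mobilekin_insufficient_data")
})

test_that("kinematics are equivariant under time shifts", {
  withr::with_seed(5, {
    v <- abs(rnorm(800)) + 0.2
    a <- displacement_rate(make_speed(v, rate_hz = 2, t0 = 0), tau = 20)
    b <- displacement_rate(make_speed(v, rate_hz = 2, t0 = 55), tau = 20)
    expect_equal(a$rate, b$rate, tolerance = 1e-12)
    expect_equal(b$t, a$t + 55)
  })
})

test_that("short marker gaps are interpolated and long ones reject the series", {
  t <- (0:599) / 60
  x <- 3 * t
  x_gap <- x; x_gap[100:115] <- NA          # 0.25 s gap
  p <- position_series(t, x_gap, 4 * t, rep(0, 600))
  expect_equal(p$x, x, tolerance = 1e-12)   # linear fill is exact here
  expect_equal(instantaneous_speed(p)$v, rep(5, 598), tolerance = 1e-12)

  x_long <- x; x_long[100:160] <- NA        # > 0.5 s
  expect_error(position_series(t, x_long, 4 * t, rep(0, 600)),
               class = "mobilekin_gap_error")
  x_edge <- x; x_edge[1] <- NA
  expect_error(position_series(t, x_edge, 4 * t, rep(0, 600)),
               class = "mobilekin_gap_error")
})

test_that("1 Hz down-sampling picks exact values at integer seconds", {
  withr::with_seed(8, {
    vals <- abs(rnorm(721 * 60))
    r <- make_rate(vals, rate_hz = 60)
    d <- downsample_1hz(r, t_grid = 0:720)
    expect_equal(d$rate, vals[seq(1, length(vals), by = 60)])
  })
})
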