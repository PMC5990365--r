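# Game physics and the artificial player.

test_that("collision law: stationary paddle reflects at 0.7 of the speed", {
  set.seed(1)
  for (i in 1:20) {
    theta <- runif(1, 0, pi)
    vin <- runif(1, 0.1, 2) * c(cos(runif(1, 0, 2 * pi)),
                                sin(runif(1, 0, 2 * pi)))
    vout <- collision_response(vin, c(0, 0), theta)
    expect_equal(sqrt(sum(vout^2)) / sqrt(sum(vin^2)), 0.7,
                 tolerance = 1e-12)
  }
})

test_that("collision law: resting ball picks up 0.42 of the paddle velocity", {
  vout <- collision_response(c(0, 0), c(1, 0), theta = pi / 2)
  expect_equal(vout, c(0.42, 0), tolerance = 1e-12)
  vout2 <- collision_response(c(0, 0), c(0.3, -0.7), theta = 1.1)
  expect_equal(vout2, 0.42 * c(0.3, -0.7), tolerance = 1e-12)
})

test_that("collision law: direct matrix arithmetic example", {
  # theta = 0 reflects the vertical component only
  vout <- collision_response(c(0.3, -1.0), c(0, 0), theta = 0)
  expect_equal(vout, c(0.21, 0.7), tolerance = 1e-12)
})

test_that("friction shortens the velocity without turning it", {
  expect_equal(apply_friction(c(0, 0), 0.1, 0.5), c(0, 0))
  v <- c(0.3, -0.4)
  v1 <- apply_friction(v, 0.2, 0.1)
  expect_lt(sqrt(sum(v1^2)), sqrt(sum(v^2)))
  expect_equal(v1 / sqrt(sum(v1^2)), v / sqrt(sum(v^2)), tolerance = 1e-12)
  # n small steps equal one big step (linear decay is additive in time)
  v_many <- v
  for (i in 1:10) v_many <- apply_friction(v_many, 0.02, 0.1)
  expect_equal(v_many, apply_friction(v, 0.2, 0.1), tolerance = 1e-12)
  # decay floors at zero rather than reversing
  expect_equal(apply_friction(c(0.01, 0), 1, 1), c(0, 0))
  expect_error(apply_friction(v, -0.1, 0.1), "non-negative")
})

test_that("bounce perturbation is uniform on +/-0.13 and reproducible", {
  set.seed(99)
  d <- bounce_perturbation(1e5)
  expect_true(all(abs(d) <= 0.13))
  expect_lt(abs(mean(d)), 3 * 0.13 / sqrt(3) / sqrt(1e5))
  set.seed(99)
  expect_identical(bounce_perturbation(1e5), d)
})

test_that("delayed view lags the trajectory and handles the boundary", {
  tt <- seq(0, 2, by = 0.005)
  hist <- data.frame(t = tt, x = 0.3 * tt, v = rep(0.3, length(tt)))
  # tau = 0: identity
  out0 <- delayed_view(hist, 0, c(0.5, 1.2))
  expect_equal(out0[, "x"], 0.3 * c(0.5, 1.2), tolerance = 1e-12)
  # constant velocity: positional lag = v tau
  out <- delayed_view(hist, 0.1, c(0.5, 1.0, 1.7))
  expect_equal(0.3 * c(0.5, 1.0, 1.7) - out[, "x"], rep(0.03, 3),
               tolerance = 1e-12)
  # before the delay line fills: initial state
  expect_equal(delayed_view(hist, 0.5, 0.2)[, "x"], c(x = 0))
  expect_error(delayed_view(data.frame(t = numeric(0), x = numeric(0)),
                            0.1, 1), "empty")
})

test_that("haptic pulse is 0.05 kg times the velocity change for 5 ms", {
  expect_equal(haptic_impulse(c(0, 0))$force, c(0, 0))
  hp <- haptic_impulse(c(1, 0), tau = 0.12)
  expect_equal(sqrt(sum(hp$force^2)), 0.05, tolerance = 1e-12)
  expect_equal(hp$duration, 0.005)
  expect_equal(hp$onset_shift, 0.12)
  expect_error(haptic_impulse(c(NA, 0)), "finite")
})

test_that("stroke placement lands the contact at the commanded phase", {
  # no jitter: contact must fall exactly offset = tau/2 + delta after the peak
  pl <- player_model(timing_offset = 0.04, timing_jitter = 0,
                     amplitude_jitter = 0)
  home <- c(0, 0)
  st <- simulate_player_stroke(pl, home, c(0.1, 0), t_contact = 1.0,
                               tau = 0.12)
  expect_equal(st$offset, 0.12 / 2 + 0.04, tolerance = 1e-12)
  expect_equal(st$t_peak, 1.0 - st$offset, tolerance = 1e-12)
  # paddle really is at the interception point at t_contact
  hs <- eventmass:::stroke_state(st, home, 1.0)
  expect_equal(hs$x, c(0.1, 0), tolerance = 1e-12)
  # and the peak-speed sample is the stroke midpoint time
  speeds <- vapply(seq(st$t_start, st$t_start + st$T_out, by = 1e-3),
                   function(t) sqrt(sum(eventmass:::stroke_state(st, home, t)$v^2)),
                   numeric(1))
  t_grid <- seq(st$t_start, st$t_start + st$T_out, by = 1e-3)
  expect_equal(t_grid[which.max(speeds)], st$t_start + st$T_out / 2,
               tolerance = 2e-3)
})

test_that("delta = 0 with zero delay and no jitter hits at the velocity peak", {
  pl <- player_model(timing_offset = 0, timing_jitter = 0)
  st <- simulate_player_stroke(pl, c(0, 0), c(0.1, 0), t_contact = 1.0,
                               tau = 0)
  expect_equal(st$t_peak, 1.0, tolerance = 1e-12)
})

test_that("late and early hits order the visual and proprioceptive speeds", {
  # on a generated stroke v_v(t) = v_p(t - tau); hitting in the deceleration
  # phase makes the delayed (visual) speed the larger one
  home <- c(0, 0)
  tau <- 0.12
  for (delta in c(0.04, -0.04)) {
    pl <- player_model(timing_offset = delta, timing_jitter = 0)
    st <- simulate_player_stroke(pl, home, c(0.1, 0), t_contact = 1.0, tau)
    v_p <- sqrt(sum(eventmass:::stroke_state(st, home, 1.0)$v^2))
    v_v <- sqrt(sum(eventmass:::stroke_state(st, home, 1.0 - tau)$v^2))
    if (delta > 0) expect_gt(v_v, v_p) else expect_lt(v_v, v_p)
  }
})

test_that("seeded sessions are exactly reproducible", {
  cfg <- pong_config("lateral_right")
  pl <- player_model(timing_offset = 0.02)
  s1 <- run_pong_session(cfg, pl, duration = 60, seed = 5)
  s2 <- run_pong_session(cfg, pl, duration = 60, seed = 5)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$misses, s2$misses)
})

test_that("zero-delay sessions have identical visual and true hit velocities", {
  cfg <- pong_config("lateral_right", delay_tau = 0)
  s <- run_pong_session(cfg, player_model(), duration = 90, seed = 8)
  expect_gt(nrow(s$hits), 5)
  expect_equal(s$hits$vvx, s$hits$vpx, tolerance = 1e-12)
  expect_equal(s$hits$vvy, s$hits$vpy, tolerance = 1e-12)
})

test_that("logged visual velocity is the trajectory velocity one delay back", {
  s <- cached_session()
  tau <- s$header$config$delay_tau
  tr <- s$trajectory
  vvx <- stats::approx(tr$t, tr$vx, xout = s$hits$t_hit - tau)$y
  vvy <- stats::approx(tr$t, tr$vy, xout = s$hits$t_hit - tau)$y
  # interpolation tolerance: the log stores the exact stroke velocity
  expect_equal(vvx, s$hits$vvx, tolerance = 1e-2)
  expect_equal(vvy, s$hits$vvy, tolerance = 1e-2)
  expect_lt(max(abs(vvx - s$hits$vvx)), 5e-4)
})

test_that("hit times lie inside the recorded support and counts match", {
  s <- cached_session()
  expect_true(all(s$hits$t_hit >= 0 & s$hits$t_hit <= s$header$duration))
  expect_equal(sum(s$hit_counts), nrow(s$hits))
})

test_that("timing taxonomy: the sign of delta sets the velocity mismatch", {
  cfg <- pong_config("lateral_right")
  mean_mismatch <- function(delta) {
    s <- run_pong_session(cfg, player_model(timing_offset = delta),
                          duration = 120, seed = 31)
    mean(sqrt(s$hits$vvx^2 + s$hits$vvy^2) -
           sqrt(s$hits$vpx^2 + s$hits$vpy^2))
  }
  m_neg <- mean_mismatch(-0.04)
  m_zero <- mean_mismatch(0)
  m_pos <- mean_mismatch(0.04)
  expect_lt(m_neg, 0)
  expect_gt(m_pos, 0)
  expect_lt(abs(m_zero), 0.05)
  expect_true(m_neg < m_zero && m_zero < m_pos)
})

test_that("session logs round-trip through the CSV/JSON store", {
  s <- cached_session()
  d <- withr::local_tempdir()
  write_session(s, d)
  s2 <- read_session(d)
  expect_equal(s2$hits, s$hits, tolerance = 1e-12)
  expect_equal(s2$trajectory$x, s$trajectory$x, tolerance = 1e-12)
  expect_equal(s2$header$config$delay_tau, s$header$config$delay_tau)
  expect_equal(s2$header$player$timing_offset, s$header$player$timing_offset)
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(pong_config(delay_tau = -0.1), "non-negative")
  expect_error(player_model(stroke_duration = -1), "positive")
  expect_error(player_model(timing_offset = 0.4, stroke_duration = 0.6),
               "half the stroke duration")
  expect_error(run_pong_session(pong_config(), player_model(), duration = -5),
               "positive")
  # a court outside the reachable workspace is refused before simulation
  bad <- pong_config("lateral_right", court_centre = c(0.6, 0.5))
  expect_error(run_pong_session(bad, player_model(), duration = 10),
               "workspace")
})
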