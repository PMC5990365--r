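# Estimation chain: filtering, hit-velocity extraction, per-modality masses,
# outlier rejection, maximum-likelihood fusion.

test_that("zero-phase Butterworth keeps DC and the passband, kills 50 Hz", {
  cfg <- filter_config()
  tt <- seq(0, 3, by = 1 / cfg$sample_rate)
  expect_equal(smooth_velocity(rep(1.3, length(tt)), cfg),
               rep(1.3, length(tt)), tolerance = 1e-6)
  mid <- seq(200, length(tt) - 200)
  hi <- sin(2 * pi * 50 * tt)
  amp_hi <- max(abs(smooth_velocity(hi, cfg)[mid]))
  expect_lt(amp_hi, 10^(-30 / 20))           # > 30 dB attenuation
  lo <- sin(2 * pi * 1 * tt)
  amp_lo <- max(abs(smooth_velocity(lo, cfg)[mid]))
  expect_equal(amp_lo, 1, tolerance = 0.01)  # passband preserved within 1%
  expect_error(smooth_velocity(rep(0, 10), cfg), "warm-up")
  expect_error(filter_config(cutoff = 120), "Nyquist")
})

test_that("extraction recovers analytic stroke velocities at hits", {
  # synthetic session with a single known minimum-jerk stroke and a fabricated
  # hit at a known phase
  fs <- 200
  tt <- seq(0, 30, by = 1 / fs)
  tau <- 0.12
  t0 <- 20; Tdur <- 0.6; A <- 0.22
  u <- pmin(pmax((tt - t0) / Tdur, 0), 1)
  vx <- A * (30 * u^2 - 60 * u^3 + 30 * u^4) / Tdur
  x <- A * (10 * u^3 - 15 * u^4 + 6 * u^5)
  traj <- data.frame(t = tt, q1 = 0, q2 = 0, x = x, y = 0, vx = vx, vy = 0)
  t_hit <- t0 + Tdur / 2 + 0.1
  hits <- data.frame(t_hit = t_hit, x = 0, y = 0, q1 = 1.9, q2 = 1.2,
                     theta = pi / 2, vpx = 0, vpy = 0, vvx = 0, vvy = 0,
                     dvx = 0, dvy = 0)
  session <- structure(list(
    header = list(config = pong_config("lateral_right", delay_tau = tau)),
    trajectory = traj, hits = hits), class = "pong_session")
  pairs <- extract_hit_velocities(session, window_min = 1)
  mj_speed <- function(t) {
    uu <- pmin(pmax((t - t0) / Tdur, 0), 1)
    A * (30 * uu^2 - 60 * uu^3 + 30 * uu^4) / Tdur
  }
  expect_equal(pairs$v_p, mj_speed(t_hit), tolerance = 1e-3)
  expect_equal(pairs$v_v, mj_speed(t_hit - tau), tolerance = 1e-3)
})

test_that("zero delay yields identical visual and proprioceptive pairs", {
  cfg <- pong_config("lateral_right", delay_tau = 0)
  s <- run_pong_session(cfg, player_model(), duration = 90, seed = 14)
  pairs <- extract_hit_velocities(s, window_min = 1.5)
  expect_equal(pairs$v_v, pairs$v_p, tolerance = 1e-9)
})

test_that("hits before one delay of recording are skipped, empty windows error", {
  s <- cached_session()
  expect_error(extract_hit_velocities(s, window_min = 1e-9), "no hits")
  # fabricate a hit earlier than tau
  s2 <- s
  s2$hits <- rbind(s$hits[1, ], s$hits)
  s2$hits$t_hit[1] <- 0.05
  pairs <- extract_hit_velocities(s2, window_min = 60)
  expect_equal(attr(pairs, "n_skipped"), 1L)
  expect_true(all(pairs$t_hit >= s$header$config$delay_tau))
})

test_that("per-modality masses follow the kinetic-energy bookkeeping", {
  em <- effective_masses_at_hit(1.5, v_v = 1.2, v_p = 1.0)
  expect_equal(em$m_v, 1.5)
  expect_equal(em$m_p, 2.16, tolerance = 1e-12)
  em2 <- effective_masses_at_hit(2.0, v_v = 0.8, v_p = 0.8)
  expect_equal(em2$m_p, em2$m_v)
  expect_error(effective_masses_at_hit(1.5, 0.5, 0), "floor")
})

test_that("per-hit modifier: sign, null, and hand-computed value", {
  expect_equal(per_hit_modifier(1.5, 1.0, 1.0), 0)
  expect_equal(per_hit_modifier(1.5, 1.2, 1.0), 0.66, tolerance = 1e-12)
  expect_lt(per_hit_modifier(1.5, 0.8, 1.0), 0)
  expect_gt(per_hit_modifier(1.5, 1.1, 1.0), 0)
  expect_error(per_hit_modifier(1.5, 1.0, 0.001), "floor")
})

test_that("modifier keeps the kinetic energy invariant across modalities", {
  set.seed(15)
  for (i in 1:50) {
    m_r <- runif(1, 0.5, 2.5)
    v_p <- runif(1, 0.1, 1.5)
    v_v <- runif(1, 0.1, 1.5)
    mh <- per_hit_modifier(m_r, v_v, v_p)
    expect_equal(0.5 * (m_r + mh) * v_p^2, 0.5 * m_r * v_v^2,
                 tolerance = 1e-12)
  }
})

test_that("modifier is monotone in the velocity ratio and scales with mass", {
  ratios <- seq(0.5, 2, by = 0.1)
  mh <- vapply(ratios, function(r) per_hit_modifier(1.5, r, 1), numeric(1))
  expect_true(all(diff(mh) > 0))
  expect_equal(per_hit_modifier(3.0, 1.2, 1.0),
               2 * per_hit_modifier(1.5, 1.2, 1.0), tolerance = 1e-12)
})

test_that("outlier filter removes only constructed outliers", {
  set.seed(16)
  m_v <- rnorm(50, 1.5, 0.1)
  m_p <- rnorm(50, 1.6, 0.08)   # well inside the 10-SD(m_v) band
  expect_true(all(filter_outlier_hits(m_v, m_p)))
  m_p2 <- m_p
  m_p2[17] <- mean(m_v) + 50 * sd(m_v)
  keep <- filter_outlier_hits(m_v, m_p2)
  expect_identical(which(!keep), 17L)
  # degenerate zero-SD visual channel: exact-match convention
  keep0 <- filter_outlier_hits(rep(1.5, 4), c(1.5, 2, 1.5, 7))
  expect_identical(keep0, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(filter_outlier_hits(rep(1.5, 4), rep(9, 4)), "all hits")
  expect_error(filter_outlier_hits(1.5, 1.5), "at least 2")
})

test_that("fusion weights are inverse-variance and bracket the means", {
  # equal variances: plain average
  a <- c(1.0, 1.2, 1.4); b <- c(2.0, 2.2, 2.4)
  est <- fuse_masses(a, b)
  expect_equal(est$E_m, (mean(a) + mean(b)) / 2, tolerance = 1e-12)
  expect_equal(est$w_v + est$w_p, 1)
  # giant proprioceptive variance: visual takes over
  set.seed(17)
  bb <- rnorm(200, 2, 50)
  est2 <- fuse_masses(a, bb)
  expect_lt(abs(est2$E_m - mean(a)), 0.05)
  # random samples stay bracketed
  for (i in 1:20) {
    x <- rnorm(20, runif(1, 0.5, 2), runif(1, 0.01, 0.5))
    y <- rnorm(20, runif(1, 0.5, 2), runif(1, 0.01, 0.5))
    e <- fuse_masses(x, y)
    expect_gte(e$E_m, min(mean(x), mean(y)) - 1e-12)
    expect_lte(e$E_m, max(mean(x), mean(y)) + 1e-12)
  }
  # degenerate variances
  est3 <- fuse_masses(c(1.5, 1.5), c(2, 3))
  expect_equal(est3$E_m, 1.5)
  expect_error(fuse_masses(c(1, 1), c(2, 2)), "zero variance")
  expect_error(fuse_masses(1.5, c(1, 2)), "at least 2")
  expect_equal(mass_modifier(est), est$E_m - mean(a), tolerance = 1e-12)
})

test_that("fused modifier is the weight-shrunken closed form at constant ratio", {
  # with a fixed velocity ratio r the per-hit modifier equals m_r (r^2 - 1)
  # exactly, and inverse-variance fusion shrinks the session modifier by the
  # proprioceptive weight: m_hat = w_p (mean m_p - mean m_v), an algebraic
  # identity of the estimator
  set.seed(18)
  m_r <- 1.5; r <- 1.15
  for (n in c(50, 400)) {
    v_p <- runif(n, 0.4, 0.9)
    v_v <- r * v_p
    mr_i <- m_r * exp(rnorm(n, 0, 0.02))   # mild configuration spread
    em <- effective_masses_at_hit(mr_i, v_v, v_p)
    expect_equal(mean(em$m_p / em$m_v), r^2, tolerance = 1e-12)
    expect_equal(per_hit_modifier(mr_i, v_v, v_p), mr_i * (r^2 - 1),
                 tolerance = 1e-12)
    est <- fuse_masses(em$m_v, em$m_p)
    expect_equal(est$m_hat, est$w_p * (mean(em$m_p) - mean(em$m_v)),
                 tolerance = 1e-12)
  }
  # Monte-Carlo over seeds: the session modifier converges to the shrunken
  # target w_p m_r (r^2 - 1) with bias -> 0 as hits accumulate
  errs <- vapply(1:30, function(s) {
    set.seed(100 + s)
    mr_i <- m_r * exp(rnorm(400, 0, 0.02))
    v_p <- runif(400, 0.4, 0.9)
    em <- effective_masses_at_hit(mr_i, r * v_p, v_p)
    est <- fuse_masses(em$m_v, em$m_p)
    est$m_hat - est$w_p * mean(em$m_v) * (r^2 - 1)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 1e-3)
  # the shrunken target has the sign and monotonicity of the full form
  m_hat_at <- function(r) {
    set.seed(55)
    mr_i <- m_r * exp(rnorm(200, 0, 0.02))
    v_p <- runif(200, 0.4, 0.9)
    em <- effective_masses_at_hit(mr_i, r * v_p, v_p)
    fuse_masses(em$m_v, em$m_p)$m_hat
  }
  ms <- vapply(c(0.85, 1, 1.15), m_hat_at, numeric(1))
  expect_lt(ms[1], 0)
  expect_equal(ms[2], 0, tolerance = 1e-10)
  expect_gt(ms[3], 0)
})

test_that("whole-session estimate recovers the timing-offset sign", {
  s <- cached_session()   # timing_offset = +0.03
  est <- session_mass_estimate(default_linkage(), s, window_min = 2.5)
  expect_gt(est$m_hat, 0)
  expect_equal(est$w_v + est$w_p, 1)
  expect_gte(est$E_m, min(mean(est$mv_samples), mean(est$mp_samples)))
  expect_lte(est$E_m, max(mean(est$mv_samples), mean(est$mp_samples)))
  # reference mass at the right-court hit region is near the calibrated 1.5
  expect_equal(est$m_r, 1.5, tolerance = 0.15)
})
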