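# Delayed virtual pong with a parametric artificial player.
#
# The game runs on a 200 Hz loop inside a square court. The ball bounces off
# the side walls and the distinguished far wall (where a uniform velocity
# perturbation is injected), slows down under linear friction, and is returned
# by a paddle tied to the simulated hand. The player is an explicit modelling
# choice: it watches the *delayed* visual ball, compensates the delay it has
# adapted to, and times reciprocal minimum-jerk strokes so that contact lands
# at a controlled offset from the stroke's velocity peak.

#' Pong game configuration
#'
#' Game constants of the delayed pong. Restitution (0.7) and paddle coupling
#' (0.42) are the collision-law coefficients; the bounce perturbation is
#' uniform on +/-0.13 m/s along the far wall; the haptic pulse is
#' \code{f = 0.05 kg * dv} for 5 ms. The visuomotor delay defaults to 80 ms
#' for the frontal court and 120 ms for the lateral courts. Serve speed and
#' friction are unprinted game constants chosen to give tens of hits per
#' minute; they are recorded in the session header.
#'
#' @param court_side one of \code{"frontal"}, \code{"lateral_right"},
#'   \code{"lateral_left"}.
#' @param court_centre numeric(2) court centre in the robot frame (m); default
#'   from \code{\link{default_geometry}}.
#' @param court_extent side of the square court (m).
#' @param delay_tau visuomotor delay (s); \code{NULL} picks the per-court
#'   default.
#' @param restitution,paddle_coupling collision-law coefficients.
#' @param bounce_noise_halfwidth half-width of the far-wall perturbation (m/s).
#' @param friction_decay linear speed-loss rate (m/s per s).
#' @param haptic_mass,haptic_duration haptic pulse constants (kg, s).
#' @param sample_rate game loop and recording rate (Hz).
#' @param ball_speed_init serve speed (m/s).
#' @param paddle_halflength half-length of the paddle segment (m).
#' @param serve_pause pause before a re-serve (s).
#' @param home_margin distance behind the court's near edge at which the
#'   paddle rests between strokes (m); keeps the resting paddle out of the
#'   ball's path so unanswered balls leave the court.
#' @param hit_refractory time after a paddle hit during which no new contact
#'   can occur (s); prevents the stroke's follow-through from double-hitting
#'   the ball it has just returned.
#' @return object of class \code{pong_config}.
#' @export
pong_config <- function(court_side = "lateral_right",
                        court_centre = NULL,
                        court_extent = 0.2,
                        delay_tau = NULL,
                        restitution = 0.7,
                        paddle_coupling = 0.42,
                        bounce_noise_halfwidth = 0.13,
                        friction_decay = 0.05,
                        haptic_mass = 0.05,
                        haptic_duration = 0.005,
                        sample_rate = 200,
                        ball_speed_init = 0.4,
                        paddle_halflength = 0.06,
                        serve_pause = 0.5,
                        home_margin = 0.04,
                        hit_refractory = 0.4) {
  court_side <- match.arg(court_side,
                          c("frontal", "lateral_right", "lateral_left"))
  if (is.null(delay_tau))
    delay_tau <- if (court_side == "frontal") 0.080 else 0.120
  if (is.null(court_centre)) {
    g <- default_geometry()
    court_centre <- switch(court_side,
                           frontal = c(g$x_mid, g$y0),
                           lateral_right = c(g$x_mid + 0.1, g$y0),
                           lateral_left = c(g$x_mid - 0.1, g$y0))
  }
  if (delay_tau < 0) stop("delay_tau must be non-negative")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (court_extent <= 0 || ball_speed_init <= 0)
    stop("court_extent and ball_speed_init must be positive")
  structure(list(court_side = court_side,
                 court_centre = as.numeric(court_centre),
                 court_extent = court_extent,
                 delay_tau = delay_tau,
                 restitution = restitution,
                 paddle_coupling = paddle_coupling,
                 bounce_noise_halfwidth = bounce_noise_halfwidth,
                 friction_decay = friction_decay,
                 haptic_mass = haptic_mass,
                 haptic_duration = haptic_duration,
                 sample_rate = sample_rate,
                 ball_speed_init = ball_speed_init,
                 paddle_halflength = paddle_halflength,
                 serve_pause = serve_pause,
                 home_margin = home_margin,
                 hit_refractory = hit_refractory),
            class = "pong_config")
}

#' Artificial player model
#'
#' Reciprocal minimum-jerk strokes timed against the predicted ball arrival.
#' \code{timing_offset} is the signed offset of intended contact relative to
#' the instant at which the visual and proprioceptive paddle speeds cross
#' (half a delay after the stroke's velocity peak; the peak itself when the
#' delay is zero). Negative, zero and positive offsets land the hits in the
#' accelerating, equal-velocity and decelerating phase of the stroke
#' respectively.
#'
#' @param stroke_amplitude nominal out-stroke amplitude (m).
#' @param stroke_duration duration of the outgoing stroke phase (s).
#' @param timing_offset signed contact-timing offset delta (s).
#' @param timing_jitter SD of per-stroke timing noise (s).
#' @param amplitude_jitter SD of per-stroke aim noise along the stroke (m).
#' @param adaptation_rate per-stroke rate at which the player's delay
#'   compensation approaches the true delay; 0 (default) means fully adapted,
#'   the end-of-adaptation regime the estimation stage consumes.
#' @return object of class \code{player_model}.
#' @export
player_model <- function(stroke_amplitude = 0.2,
                         stroke_duration = 0.6,
                         timing_offset = 0,
                         timing_jitter = 0.02,
                         amplitude_jitter = 0.01,
                         adaptation_rate = 0) {
  if (stroke_duration <= 0) stop("stroke_duration must be positive")
  if (abs(timing_offset) >= stroke_duration / 2)
    stop("|timing_offset| must be smaller than half the stroke duration")
  structure(list(stroke_amplitude = stroke_amplitude,
                 stroke_duration = stroke_duration,
                 timing_offset = timing_offset,
                 timing_jitter = timing_jitter,
                 amplitude_jitter = amplitude_jitter,
                 adaptation_rate = adaptation_rate),
            class = "player_model")
}

#' Ball-paddle collision response
#'
#' \code{v_out = 0.7 R(theta) v_in + 0.42 v_paddle}, with \code{R(theta)} the
#' reflection matrix about the paddle line at orientation \code{theta}.
#'
#' @param v_ball_in numeric(2) incoming ball velocity (m/s).
#' @param v_paddle numeric(2) paddle velocity at contact (m/s).
#' @param theta paddle orientation w.r.t. the horizontal axis (rad).
#' @param restitution,coupling law coefficients.
#' @return numeric(2) outgoing ball velocity (m/s).
#' @export
collision_response <- function(v_ball_in, v_paddle, theta,
                               restitution = 0.7, coupling = 0.42) {
  R <- matrix(c(cos(2 * theta), sin(2 * theta),
                sin(2 * theta), -cos(2 * theta)), 2, 2)
  drop(restitution * R %*% v_ball_in) + coupling * v_paddle
}

#' Linear friction decay of the ball speed
#'
#' Reduces the speed by \code{rate * dt} along the current heading, floored at
#' zero; the direction is unchanged.
#'
#' @param v_ball numeric(2) ball velocity (m/s).
#' @param dt time step (s), non-negative.
#' @param rate speed-loss rate (m/s per s).
#' @return numeric(2) decayed velocity.
#' @export
apply_friction <- function(v_ball, dt, rate) {
  if (dt < 0) stop("dt must be non-negative")
  sp <- sqrt(sum(v_ball^2))
  if (sp == 0) return(v_ball)
  v_ball * max(sp - rate * dt, 0) / sp
}

#' Far-wall bounce perturbation
#'
#' Uniform draw on +/-halfwidth (m/s), added to the velocity component along
#' the bouncing wall at far-wall bounces. Uses R's global RNG stream, so a
#' seeded session reproduces the same sequence.
#'
#' @param n number of draws.
#' @param halfwidth support half-width (m/s).
#' @return numeric(n).
#' @export
bounce_perturbation <- function(n = 1, halfwidth = 0.13) {
  stats::runif(n, -halfwidth, halfwidth)
}

#' Haptic collision pulse
#'
#' \code{f = mb * dv} rendered for a fixed duration; in delayed sessions the
#' pulse is presented one delay after the physical contact, like every other
#' feedback channel.
#'
#' @param delta_v_ball numeric(2) ball velocity change at the collision (m/s).
#' @param mb haptic mass constant (kg).
#' @param duration pulse duration (s).
#' @param tau delay applied to the pulse onset (s).
#' @return list with \code{force} (N), \code{duration} (s), \code{onset_shift}
#'   (s).
#' @export
haptic_impulse <- function(delta_v_ball, mb = 0.05, duration = 0.005,
                           tau = 0) {
  if (any(!is.finite(delta_v_ball))) stop("delta_v must be finite")
  list(force = mb * as.numeric(delta_v_ball), duration = duration,
       onset_shift = tau)
}

#' Delayed view of a sampled trajectory
#'
#' Returns the state at \code{t - tau} by linear interpolation between
#' samples; for \code{t < tau} the initial state is returned (the screen shows
#' the first frame until the delay line fills).
#'
#' @param history data.frame or list with a time column \code{t} and one or
#'   more state columns.
#' @param tau delay (s).
#' @param t query time(s) (s); vectorized.
#' @param cols state columns to return (default: all but \code{t}).
#' @return matrix of interpolated states, one row per query time.
#' @export
delayed_view <- function(history, tau, t, cols = NULL) {
  ht <- history$t
  if (is.null(ht) || length(ht) == 0) stop("empty history")
  if (is.null(cols)) cols <- setdiff(names(history), "t")
  tq <- pmax(t - tau, ht[1])
  out <- vapply(cols, function(cn) {
    stats::approx(ht, history[[cn]], xout = tq, rule = 2)$y
  }, numeric(length(t)))
  matrix(out, nrow = length(t), dimnames = list(NULL, cols))
}

# Court frame: outward hit axis a, transverse axis b, paddle orientation.
court_frame <- function(config) {
  switch(config$court_side,
         frontal = list(a = c(0, 1), b = c(1, 0), theta = 0),
         lateral_right = list(a = c(1, 0), b = c(0, 1), theta = pi / 2),
         lateral_left = list(a = c(-1, 0), b = c(0, 1), theta = pi / 2))
}

# Fold a transverse coordinate into [-half, half] by wall reflections.
fold_coord <- function(w, half) {
  z <- (w + half) %% (4 * half)
  ifelse(z > 2 * half, 4 * half - z, z) - half
}

#' Plan one reciprocal minimum-jerk stroke
#'
#' Places an out-and-back minimum-jerk stroke from the home position so the
#' paddle passes through the predicted interception point exactly at
#' \code{t_contact}, with the contact landing \code{tau/2 + timing_offset (+
#' jitter)} after the stroke's velocity peak. Returns \code{NULL} when no
#' valid stroke exists (too late, offset outside the stroke, or apex out of
#' the workspace check range).
#'
#' @param player a \code{\link{player_model}}.
#' @param home numeric(2) stroke start/return position (m).
#' @param contact_point numeric(2) predicted interception point (m).
#' @param t_contact predicted contact time (s).
#' @param tau session delay (s).
#' @return stroke object (list) or \code{NULL}.
#' @export
simulate_player_stroke <- function(player, home, contact_point, t_contact,
                                   tau) {
  delta_eff <- player$timing_offset +
    stats::rnorm(1, 0, player$timing_jitter)
  offset <- tau / 2 + delta_eff
  T_out <- player$stroke_duration
  if (abs(offset) >= 0.45 * T_out) return(NULL)
  aim <- contact_point - home
  aim_len <- sqrt(sum(aim^2))
  if (aim_len < 1e-6) return(NULL)
  aim <- aim + (aim / aim_len) * stats::rnorm(1, 0, player$amplitude_jitter)
  frac <- mj_sigma(0.5 + offset / T_out)
  if (frac < 0.15) return(NULL)
  apex <- home + aim / frac
  if (sqrt(sum((apex - home)^2)) > 3 * player$stroke_amplitude) return(NULL)
  t_peak <- t_contact - offset
  list(t_start = t_peak - T_out / 2,
       T_out = T_out, T_ret = T_out,
       home = home, apex = apex,
       t_peak = t_peak, offset = offset)
}

# Hand state under a stroke (or at home) at time t: closed-form evaluation.
stroke_state <- function(stroke, home, t) {
  if (is.null(stroke) || t < stroke$t_start)
    return(list(x = home, v = c(0, 0)))
  s <- t - stroke$t_start
  if (s <= stroke$T_out) {
    u <- s / stroke$T_out
    d <- stroke$apex - stroke$home
    list(x = stroke$home + d * mj_sigma(u),
         v = d * mj_dsigma(u) / stroke$T_out)
  } else if (s <= stroke$T_out + stroke$T_ret) {
    u <- (s - stroke$T_out) / stroke$T_ret
    d <- stroke$home - stroke$apex
    list(x = stroke$apex + d * mj_sigma(u),
         v = d * mj_dsigma(u) / stroke$T_ret)
  } else {
    list(x = stroke$home, v = c(0, 0))
  }
}

# Hand state at time t given the full stroke record (for the delayed channel
# and hit logging).
hand_state_at <- function(strokes, home, t) {
  for (st in strokes) {
    if (t >= st$t_start && t <= st$t_start + st$T_out + st$T_ret)
      return(stroke_state(st, home, t))
  }
  list(x = home, v = c(0, 0))
}

# Advance an estimated ball state by `horizon` seconds under friction and wall
# reflections (no bounce noise: the player cannot predict it). Small-step
# integration on the game grid.
advance_ball_estimate <- function(pos, vel, horizon, config, frame) {
  dt <- 1 / config$sample_rate
  half <- config$court_extent / 2
  C <- config$court_centre
  n <- max(0L, as.integer(round(horizon / dt)))
  for (i in seq_len(n)) {
    pos <- pos + vel * dt
    vel <- apply_friction(vel, dt, config$friction_decay)
    s <- sum((pos - C) * frame$a)
    w <- sum((pos - C) * frame$b)
    va <- sum(vel * frame$a)
    vb <- sum(vel * frame$b)
    if (s > half && va > 0) { s <- 2 * half - s; va <- -va }
    if (abs(w) > half) {
      vb <- if (w > 0) -abs(vb) else abs(vb)
      w <- fold_coord(w, half)
    }
    pos <- C + s * frame$a + w * frame$b
    vel <- va * frame$a + vb * frame$b
  }
  list(pos = pos, vel = vel)
}

#' Run one synthetic pong session
#'
#' Full event-driven simulation of the delayed pong: ball flight with linear
#' friction, side- and far-wall bounces (with the far-wall velocity
#' perturbation), artificial-player strokes, collision responses, the delayed
#' visual channel, and haptic pulses. Trajectories are recorded at the game
#' rate; identical (config, player, seed) reproduce identical logs.
#'
#' @param config a \code{\link{pong_config}}.
#' @param player a \code{\link{player_model}}.
#' @param duration session length (s), positive.
#' @param seed integer RNG seed.
#' @param params linkage parameters used to express the hand in joint space.
#' @return object of class \code{pong_session}: header, trajectory table
#'   (200 Hz), hit table, haptic table, per-minute hit counts, miss and stroke
#'   counters.
#' @export
run_pong_session <- function(config, player, duration = 360, seed = 1,
                             params = default_linkage()) {
  stopifnot(inherits(config, "pong_config"), inherits(player, "player_model"))
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  dt <- 1 / config$sample_rate
  n <- as.integer(round(duration * config$sample_rate))
  frame <- court_frame(config)
  C <- config$court_centre
  half <- config$court_extent / 2
  tau <- config$delay_tau
  home <- C - (half + config$home_margin) * frame$a
  # verify the court (and home) are inside the workspace before simulating
  for (pt in list(home, C, C + half * frame$a,
                  C + half * frame$b, C - half * frame$b)) {
    q <- inverse_kinematics(params, pt)   # errors out if unreachable
  }

  ax <- frame$a[1]; ay <- frame$a[2]
  bx <- frame$b[1]; by <- frame$b[2]

  hand_x <- matrix(0, n, 2); hand_v <- matrix(0, n, 2)
  ball_x <- matrix(0, n, 2); ball_v <- matrix(0, n, 2)
  tgrid <- (seq_len(n) - 1L) * dt

  # ball state: starts with a serve after an initial pause
  bpos <- C; bvel <- c(0, 0)
  serving_until <- config$serve_pause
  delay_steps <- as.integer(round(tau / dt))

  cur_stroke <- NULL
  strokes <- list()
  pass_planned <- FALSE
  n_strokes <- 0L
  misses <- 0L
  comp <- if (player$adaptation_rate == 0) tau else 0

  hits <- list()
  haptics <- list()

  s_prev_gap <- NA_real_
  bpos_prev <- bpos
  t_last_hit <- -Inf

  for (k in seq_len(n)) {
    t <- tgrid[k]

    # --- hand ---
    hs <- stroke_state(cur_stroke, home, t)
    if (!is.null(cur_stroke) &&
        t > cur_stroke$t_start + cur_stroke$T_out + cur_stroke$T_ret)
      cur_stroke <- NULL
    hand_x[k, ] <- hs$x; hand_v[k, ] <- hs$v

    # --- ball flight ---
    if (serving_until >= 0) {
      if (t >= serving_until) {
        alpha <- stats::runif(1, -0.5, 0.5)
        bvel <- config$ball_speed_init *
          (cos(alpha) * frame$a + sin(alpha) * frame$b)
        serving_until <- -1
        pass_planned <- FALSE
      }
    } else {
      bpos_prev <- bpos
      bpos <- bpos + bvel * dt
      bvel <- apply_friction(bvel, dt, config$friction_decay)
      s <- (bpos[1] - C[1]) * ax + (bpos[2] - C[2]) * ay
      w <- (bpos[1] - C[1]) * bx + (bpos[2] - C[2]) * by
      va <- bvel[1] * ax + bvel[2] * ay
      vb <- bvel[1] * bx + bvel[2] * by
      # far wall: reflect + inject the along-wall perturbation
      if (s > half && va > 0) {
        s <- 2 * half - s
        va <- -va
        vb <- vb + bounce_perturbation(1, config$bounce_noise_halfwidth)
      }
      # side walls: plain reflection
      if (abs(w) > half) {
        vb <- if (w > 0) -abs(vb) else abs(vb)
        w <- fold_coord(w, half)
      }
      bpos <- C + s * frame$a + w * frame$b
      bvel <- va * frame$a + vb * frame$b

      # near edge: miss -> re-serve from the centre after a pause;
      # a ball killed by friction mid-court is re-served too
      if (s < -half || sqrt(sum(bvel^2)) < 0.02) {
        if (s < -half) misses <- misses + 1L
        bpos <- C; bvel <- c(0, 0)
        serving_until <- t + config$serve_pause
        s_prev_gap <- NA_real_
      }
    }
    ball_x[k, ] <- bpos; ball_v[k, ] <- bvel

    # --- contact detection (ball incoming, crosses the paddle plane) ---
    va_now <- bvel[1] * ax + bvel[2] * ay
    if (serving_until < 0 && va_now < 0 &&
        t - t_last_hit >= config$hit_refractory) {
      s_ball <- (bpos[1] - C[1]) * ax + (bpos[2] - C[2]) * ay
      s_hand <- (hs$x[1] - C[1]) * ax + (hs$x[2] - C[2]) * ay
      gap <- s_ball - s_hand
      if (!is.na(s_prev_gap) && s_prev_gap > 0 && gap <= 0) {
        alpha <- s_prev_gap / (s_prev_gap - gap)
        t_hit <- tgrid[k - 1L] + alpha * dt
        hh <- hand_state_at(strokes_all(strokes, cur_stroke), home, t_hit)
        xb_hit <- bpos_prev + alpha * (bpos - bpos_prev)
        w_ball <- (xb_hit[1] - C[1]) * bx + (xb_hit[2] - C[2]) * by
        w_hand <- (hh$x[1] - C[1]) * bx + (hh$x[2] - C[2]) * by
        if (abs(w_ball - w_hand) <= config$paddle_halflength) {
          v_in <- bvel
          v_out <- collision_response(v_in, hh$v, frame$theta,
                                      config$restitution,
                                      config$paddle_coupling)
          hv_del <- hand_state_at(strokes_all(strokes, cur_stroke), home,
                                  t_hit - tau)
          dvb <- v_out - v_in
          q_hit <- inverse_kinematics(params, hh$x)
          hits[[length(hits) + 1L]] <- c(
            t_hit, hh$x, q_hit, frame$theta, hh$v, hv_del$v, dvb)
          hp <- haptic_impulse(dvb, config$haptic_mass,
                               config$haptic_duration, tau)
          haptics[[length(haptics) + 1L]] <- c(t_hit + tau, hp$force,
                                               hp$duration)
          bvel <- v_out
          bpos <- xb_hit + v_out * ((1 - alpha) * dt)
          ball_x[k, ] <- bpos; ball_v[k, ] <- bvel
          pass_planned <- FALSE
          t_last_hit <- t_hit
        }
      }
      s_prev_gap <- gap
    } else {
      s_prev_gap <- NA_real_
    }

    # --- player planning ---
    # Attempt whenever the hand is free and no stroke has been committed (or
    # written off) for the upcoming contact. The player works from the
    # delayed visual ball, advanced by its learned delay compensation, and
    # anticipates the far-wall bounce: the bounce perturbation is transverse,
    # so arrival timing at the interception line is predictable before the
    # bounce, while the aim carries the unpredicted perturbation.
    if (!pass_planned && serving_until < 0 && is.null(cur_stroke) &&
        k > delay_steps + 1L) {
      kv <- k - delay_steps
      vis_p <- ball_x[kv, ]; vis_v <- ball_v[kv, ]
      if (sqrt(sum(vis_v^2)) > 1e-9) {
        est <- advance_ball_estimate(vis_p, vis_v, comp, config, frame)
        va_e <- sum(est$vel * frame$a)
        s_e <- sum((est$pos - C) * frame$a)
        sp0 <- sqrt(sum(est$vel^2))
        # axis distance still to cover before reaching the interception line
        d_axis <- if (va_e < 0) s_e else 2 * half - s_e
        if (sp0 > 1e-9 && abs(va_e) > 1e-9 && d_axis > 0.01) {
          r <- config$friction_decay
          # path-length parametrization: ell(t) = sp0 t - r t^2 / 2, with the
          # axis share |va_e|/sp0 of it; first t with axis progress = d_axis
          t_c <- NA_real_
          va_abs <- abs(va_e)
          if (r > 0) {
            disc <- va_abs^2 - 2 * va_abs * r / sp0 * d_axis
            if (disc >= 0)
              t_c <- (va_abs - sqrt(disc)) / (va_abs * r / sp0)
          } else t_c <- d_axis / va_abs
          if (is.finite(t_c) && t_c > 0) {
            vb_e <- sum(est$vel * frame$b)
            w_e <- sum((est$pos - C) * frame$b)
            w_c <- fold_coord(w_e + vb_e * (t_c - r * t_c^2 / (2 * sp0)),
                              half)
            contact_pt <- C + w_c * frame$b
            st <- simulate_player_stroke(player, home, contact_pt,
                                         t + t_c, tau)
            if (!is.null(st) && st$t_start >= t + dt) {
              cur_stroke <- st
              strokes[[length(strokes) + 1L]] <- st
              n_strokes <- n_strokes + 1L
              if (player$adaptation_rate > 0)
                comp <- tau * (1 - exp(-player$adaptation_rate * n_strokes))
            }
            # whether committed or too late, this pass is decided
            pass_planned <- TRUE
          }
        }
      }
    }
  }

  # joint angles for the recorded hand path (vectorized IK)
  qtraj <- inverse_kinematics_vec(params, hand_x)
  traj <- data.frame(t = tgrid,
                     q1 = qtraj[, 1], q2 = qtraj[, 2],
                     x = hand_x[, 1], y = hand_x[, 2],
                     vx = hand_v[, 1], vy = hand_v[, 2])
  vis <- delayed_view(traj, tau, tgrid, cols = c("x", "y", "vx", "vy"))
  traj$xv <- vis[, "x"]; traj$yv <- vis[, "y"]
  traj$vxv <- vis[, "vx"]; traj$vyv <- vis[, "vy"]

  hit_df <- if (length(hits)) {
    m <- do.call(rbind, hits)
    colnames(m) <- c("t_hit", "x", "y", "q1", "q2", "theta",
                     "vpx", "vpy", "vvx", "vvy", "dvx", "dvy")
    as.data.frame(m)
  } else {
    as.data.frame(matrix(numeric(0), 0, 12,
                         dimnames = list(NULL, c("t_hit", "x", "y", "q1",
                                                 "q2", "theta", "vpx", "vpy",
                                                 "vvx", "vvy", "dvx", "dvy"))))
  }
  hap_df <- if (length(haptics)) {
    m <- do.call(rbind, haptics)
    colnames(m) <- c("t", "fx", "fy", "duration")
    as.data.frame(m)
  } else {
    as.data.frame(matrix(numeric(0), 0, 4,
                         dimnames = list(NULL, c("t", "fx", "fy", "duration"))))
  }
  minutes <- floor(hit_df$t_hit / 60)
  hit_counts <- if (nrow(hit_df))
    as.integer(table(factor(minutes, levels = 0:floor((duration - 1e-9) / 60))))
  else integer(ceiling(duration / 60))

  structure(list(
    header = list(config = config, player = player, seed = seed,
                  duration = duration),
    trajectory = traj,
    hits = hit_df,
    haptics = hap_df,
    hit_counts = hit_counts,
    misses = misses,
    n_strokes = n_strokes
  ), class = "pong_session")
}

# All strokes including the active one, most recent first.
strokes_all <- function(strokes, cur) {
  if (is.null(cur)) rev(strokes) else c(list(cur), rev(strokes))
}

#' @export
print.pong_session <- function(x, ...) {
  cat(sprintf("Pong session: %s court, tau = %.0f ms, %.1f min\n",
              x$header$config$court_side, 1000 * x$header$config$delay_tau,
              x$header$duration / 60))
  cat(sprintf("  %d hits (%s per minute), %d misses, %d strokes\n",
              nrow(x$hits), paste(x$hit_counts, collapse = ", "),
              x$misses, x$n_strokes))
  invisible(x)
}

# Vectorized elbow-out inverse kinematics for an n x 2 matrix of positions.
inverse_kinematics_vec <- function(params, X) {
  b <- base_joints(params)
  l <- params$proximal_lengths
  s <- params$distal_lengths
  out <- matrix(0, nrow(X), 2)
  for (arm in 1:2) {
    A <- if (arm == 1) b$A1 else b$A2
    dx <- X[, 1] - A[1]; dy <- X[, 2] - A[2]
    D2 <- dx^2 + dy^2; D <- sqrt(D2)
    if (any(D >= l[arm] + s[arm] | D <= abs(l[arm] - s[arm])))
      stop("workspace error in trajectory inverse kinematics")
    a <- (l[arm]^2 - s[arm]^2 + D2) / (2 * D)
    h <- sqrt(pmax(l[arm]^2 - a^2, 0))
    sgn <- if (arm == 1) 1 else -1
    Ex <- A[1] + (a * dx + sgn * h * -dy) / D
    Ey <- A[2] + (a * dy + sgn * h * dx) / D
    out[, arm] <- atan2(Ey - A[2], Ex - A[1])
  }
  out
}
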