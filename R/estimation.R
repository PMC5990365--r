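# Event-based mass estimation: per-modality effective masses at hits,
# maximum-likelihood fusion, and the mass modifier.

#' Velocity filter configuration
#'
#' Fifth-order Butterworth low-pass at 20 Hz on the 200 Hz recording grid,
#' applied forward-backward (zero phase) so hit-time velocities are not
#' phase-shifted.
#'
#' @param order filter order.
#' @param cutoff cutoff frequency (Hz), below Nyquist.
#' @param sample_rate sampling rate (Hz).
#' @return object of class \code{filter_config}.
#' @export
filter_config <- function(order = 5, cutoff = 20, sample_rate = 200) {
  if (cutoff >= sample_rate / 2) stop("cutoff must be below Nyquist")
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate),
            class = "filter_config")
}

#' Zero-phase Butterworth smoothing of a velocity signal
#'
#' @param x uniformly sampled signal at \code{cfg$sample_rate}.
#' @param cfg a \code{\link{filter_config}}.
#' @return filtered signal, same length.
#' @export
smooth_velocity <- function(x, cfg = filter_config()) {
  n <- length(x)
  if (n < 6 * (cfg$order + 1))
    stop("signal shorter than the filter warm-up")
  bf <- signal::butter(cfg$order, cfg$cutoff / (cfg$sample_rate / 2),
                       type = "low")
  # odd-reflection padding suppresses the zero-initial-condition transients of
  # the forward-backward pass at both ends
  np <- min(n - 1L, 100L)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

#' Extract paired visual/proprioceptive hit velocities from a session
#'
#' Smooths the recorded hand velocity, then per hit evaluates the
#' proprioceptive velocity at the hit time and the visual velocity as the
#' smoothed hand velocity one delay earlier, both projected on the
#' instantaneous direction of motion at the hit. Hits earlier than one delay
#' after session start are skipped; only hits inside the trailing analysis
#' window are used.
#'
#' @param session a \code{pong_session}.
#' @param tau delay (s); defaults to the session's configured delay.
#' @param window_min trailing window (minutes) of the session to analyse.
#' @param cfg a \code{\link{filter_config}}.
#' @return data.frame with one row per retained hit: \code{t_hit}, \code{q1},
#'   \code{q2}, \code{theta_dir}, \code{v_v}, \code{v_p}, and the count of
#'   skipped early hits as attribute \code{"n_skipped"}.
#' @export
extract_hit_velocities <- function(session, tau = NULL, window_min = 5,
                                   cfg = filter_config()) {
  if (is.null(tau)) tau <- session$header$config$delay_tau
  traj <- session$trajectory
  hits <- session$hits
  t_end <- max(traj$t)
  t0 <- max(0, t_end - window_min * 60)
  keep <- hits$t_hit >= t0
  skipped <- sum(keep & hits$t_hit < tau)
  keep <- keep & hits$t_hit >= tau
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) stop("no hits inside the analysis window")
  vx <- smooth_velocity(traj$vx, cfg)
  vy <- smooth_velocity(traj$vy, cfg)
  vpx <- stats::approx(traj$t, vx, xout = hits$t_hit)$y
  vpy <- stats::approx(traj$t, vy, xout = hits$t_hit)$y
  vvx <- stats::approx(traj$t, vx, xout = hits$t_hit - tau)$y
  vvy <- stats::approx(traj$t, vy, xout = hits$t_hit - tau)$y
  sp <- sqrt(vpx^2 + vpy^2)
  theta_dir <- atan2(vpy, vpx)
  out <- data.frame(t_hit = hits$t_hit, q1 = hits$q1, q2 = hits$q2,
                    theta_dir = theta_dir,
                    v_v = (vvx * vpx + vvy * vpy) / sp,
                    v_p = sp)
  attr(out, "n_skipped") <- skipped
  out
}

#' Per-modality effective masses at a hit
#'
#' The visual effective mass equals the reference effective mass of the
#' linkage at the hit configuration along the motion direction; the
#' proprioceptive effective mass is scaled by the squared velocity ratio so
#' that the kinetic energy estimate is invariant across modalities.
#'
#' @param m_r reference effective mass (kg); vectorized.
#' @param v_v,v_p visual and proprioceptive speeds along the motion direction
#'   (m/s).
#' @param speed_floor hits with \code{v_p} below this are rejected (m/s).
#' @return list with \code{m_v}, \code{m_p}.
#' @export
effective_masses_at_hit <- function(m_r, v_v, v_p, speed_floor = 0.02) {
  if (any(v_p < speed_floor))
    stop(sprintf("%d hit(s) below the %.2f m/s speed floor; reject before use",
                 sum(v_p < speed_floor), speed_floor))
  list(m_v = rep_len(m_r, length(v_p)), m_p = m_r * v_v^2 / v_p^2)
}

#' Remove proprioceptive-mass outliers
#'
#' Drops hits whose proprioceptive effective mass deviates from the mean
#' visual effective mass by more than \code{k} standard deviations of the
#' visual effective mass. When the visual masses are constant (zero SD), only
#' hits with \code{m_p} equal to the mean are retained.
#'
#' @param m_v,m_p per-hit effective masses (kg).
#' @param k rejection threshold in visual-mass SDs.
#' @return logical vector of retained hits; errors if all hits are removed.
#' @export
filter_outlier_hits <- function(m_v, m_p, k = 10) {
  if (length(m_v) < 2) stop("need at least 2 hits")
  mu <- mean(m_v)
  sdv <- stats::sd(m_v)
  keep <- if (sdv == 0) m_p == mu else abs(m_p - mu) <= k * sdv
  if (!any(keep)) stop("all hits removed by the outlier filter")
  keep
}

#' Maximum-likelihood fusion of the two mass channels
#'
#' Inverse-variance weighting of the visual and proprioceptive per-hit mass
#' samples: \code{E(m) = w_v mean(m_v) + w_p mean(m_p)} with weights
#' proportional to the reciprocal sample variances over hits. A channel with
#' zero variance takes all the weight; two zero-variance channels are an
#' error.
#'
#' @param mv_samples,mp_samples per-hit mass samples (kg), length >= 2 each.
#' @return object of class \code{mass_estimate}: means, variances, weights,
#'   fused mass \code{E_m}, reference mass \code{m_r} (mean visual mass) and
#'   mass modifier \code{m_hat = E_m - m_r}.
#' @export
fuse_masses <- function(mv_samples, mp_samples) {
  if (length(mv_samples) < 2 || length(mp_samples) < 2)
    stop("need at least 2 samples per channel")
  if (any(!is.finite(mv_samples)) || any(!is.finite(mp_samples)))
    stop("mass samples must be finite")
  sv2 <- stats::var(mv_samples)
  sp2 <- stats::var(mp_samples)
  if (sv2 == 0 && sp2 == 0) stop("zero variance in both channels")
  if (sv2 == 0) { wv <- 1; wp <- 0 }
  else if (sp2 == 0) { wv <- 0; wp <- 1 }
  else {
    wv <- (1 / sv2) / (1 / sv2 + 1 / sp2)
    wp <- 1 - wv
  }
  m_r <- mean(mv_samples)
  E_m <- wv * mean(mv_samples) + wp * mean(mp_samples)
  structure(list(m_r = m_r,
                 mv_samples = mv_samples, mp_samples = mp_samples,
                 sigma_v2 = sv2, sigma_p2 = sp2,
                 w_v = wv, w_p = wp,
                 E_m = E_m, m_hat = E_m - m_r),
            class = "mass_estimate")
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf("Mass estimate over %d hits\n", length(x$mv_samples)))
  cat(sprintf("  visual:        mean %.3f kg, var %.4g (weight %.3f)\n",
              mean(x$mv_samples), x$sigma_v2, x$w_v))
  cat(sprintf("  proprioceptive: mean %.3f kg, var %.4g (weight %.3f)\n",
              mean(x$mp_samples), x$sigma_p2, x$w_p))
  cat(sprintf("  fused E(m) = %.3f kg, mass modifier = %+.3f kg\n",
              x$E_m, x$m_hat))
  invisible(x)
}

#' Mass modifier of a fused estimate, and its per-hit form
#'
#' \code{mass_modifier} returns \code{E(m) - m_r} for a fused estimate.
#' \code{per_hit_modifier} evaluates the closed per-hit form
#' \code{m_r (v_v^2 - v_p^2) / v_p^2}, whose sign follows the sign of
#' \code{|v_v| - |v_p|}: zero at equal speeds, positive when the visual speed
#' exceeds the proprioceptive speed.
#'
#' @param estimate a \code{mass_estimate}.
#' @param m_r reference effective mass (kg).
#' @return mass modifier (kg).
#' @export
mass_modifier <- function(estimate, m_r = estimate$m_r) {
  estimate$E_m - m_r
}

#' @rdname mass_modifier
#' @param v_v,v_p speeds along the motion direction at the hit (m/s).
#' @param speed_floor rejection floor on \code{v_p} (m/s).
#' @export
per_hit_modifier <- function(m_r, v_v, v_p, speed_floor = 0.02) {
  if (any(v_p < speed_floor))
    stop("v_p below the speed floor; hit must be rejected, not divided")
  m_r * (v_v^2 - v_p^2) / v_p^2
}

#' Full per-session mass estimate
#'
#' Runs the whole estimation chain on one session: hit-velocity extraction in
#' the trailing window, per-hit reference effective mass at the hit
#' configuration along the motion direction, per-modality masses, speed-floor
#' and outlier rejection, and maximum-likelihood fusion.
#'
#' @param params linkage parameters (the true robot model).
#' @param session a \code{pong_session}.
#' @param tau delay (s); defaults to the session's.
#' @param window_min trailing analysis window (minutes).
#' @param cfg a \code{\link{filter_config}}.
#' @param speed_floor minimum proprioceptive speed for a hit to enter the
#'   modifier formula (m/s).
#' @return a \code{mass_estimate} with extra fields \code{n_hits_retained},
#'   \code{n_hits_removed}.
#' @export
session_mass_estimate <- function(params, session, tau = NULL,
                                  window_min = 5, cfg = filter_config(),
                                  speed_floor = 0.02) {
  pairs <- extract_hit_velocities(session, tau, window_min, cfg)
  ok <- pairs$v_p >= speed_floor
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 2) stop("fewer than 2 usable hits in the window")
  m_r <- vapply(seq_len(nrow(pairs)), function(i) {
    effective_mass(params, c(pairs$q1[i], pairs$q2[i]), pairs$theta_dir[i])
  }, numeric(1))
  em <- effective_masses_at_hit(m_r, pairs$v_v, pairs$v_p, speed_floor)
  keep <- filter_outlier_hits(em$m_v, em$m_p)
  est <- fuse_masses(em$m_v[keep], em$m_p[keep])
  est$n_hits_retained <- sum(keep)
  est$n_hits_removed <- sum(!keep) + sum(!ok)
  est
}
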