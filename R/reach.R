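# Blind-reach prediction: minimum-jerk plans, inverse dynamics on the
# mass-augmented model, open-loop replay on the true model.

# Quintic minimum-jerk basis on u in [0, 1] and its first two derivatives.
mj_sigma <- function(u) 10 * u^3 - 15 * u^4 + 6 * u^5
mj_dsigma <- function(u) 30 * u^2 - 60 * u^3 + 30 * u^4
mj_ddsigma <- function(u) 60 * u - 180 * u^2 + 120 * u^3

#' Minimum-jerk point-to-point trajectory
#'
#' Straight-line path with the quintic time profile that minimizes integrated
#' squared jerk; velocity and acceleration vanish at both ends, and peak speed
#' is (15/8) D/T at mid-movement.
#'
#' @param start,target numeric(2) endpoints (m).
#' @param duration movement time T (s), positive.
#' @param t time(s) at which to evaluate, in [0, T]; vectorized.
#' @return list with \code{x}, \code{v}, \code{a}: n x 2 matrices of position,
#'   velocity and acceleration.
#' @export
minimum_jerk <- function(start, target, duration, t) {
  if (duration <= 0) stop("duration must be positive")
  u <- pmin(pmax(t / duration, 0), 1)
  d <- target - start
  list(
    x = cbind(start[1] + d[1] * mj_sigma(u), start[2] + d[2] * mj_sigma(u)),
    v = cbind(d[1] * mj_dsigma(u), d[2] * mj_dsigma(u)) / duration,
    a = cbind(d[1] * mj_ddsigma(u), d[2] * mj_ddsigma(u)) / duration^2
  )
}

#' Reach specification
#'
#' @param start,target numeric(2) endpoint positions (m).
#' @param duration movement time (s).
#' @return object of class \code{reach_spec}.
#' @export
reach_spec <- function(start, target, duration = 0.6) {
  if (duration <= 0) stop("duration must be positive")
  structure(list(start = as.numeric(start), target = as.numeric(target),
                 duration = duration,
                 distance = sqrt(sum((target - start)^2))),
            class = "reach_spec")
}

# Joint-space plan for a Cartesian minimum-jerk reach: q by inverse
# kinematics, qdot through the Jacobian, qddot through the Jacobian and its
# directional derivative (so inverse dynamics sees analytic derivatives, not
# finite differences of sampled angles).
plan_joint_trajectory <- function(params, spec, sample_rate = 200) {
  t <- seq(0, spec$duration, by = 1 / sample_rate)
  mj <- minimum_jerk(spec$start, spec$target, spec$duration, t)
  n <- length(t)
  q <- qd <- qdd <- matrix(0, n, 2)
  eps <- 1e-6
  for (i in seq_len(n)) {
    qi <- inverse_kinematics(params, mj$x[i, ])
    J <- jacobian(params, qi)
    qdi <- solve(J, mj$v[i, ])
    Jdot <- (five_bar_rates(params, qi + eps * qdi)$J -
               five_bar_rates(params, qi - eps * qdi)$J) / (2 * eps)
    q[i, ] <- qi
    qd[i, ] <- qdi
    qdd[i, ] <- solve(J, mj$a[i, ] - drop(Jdot %*% qdi))
  }
  list(t = t, q = q, qdot = qd, qddot = qdd, x = mj$x)
}

#' Augment the linkage model with a perceived mass modifier
#'
#' Adds the mass modifier as a point mass at the handle, which raises the
#' effective endpoint mass by exactly \code{m_hat} in every configuration and
#' direction (the only placement consistent with the effective-mass
#' definition). The augmented set describes a perceptual internal model, so
#' the handle lump may go negative as long as the total inertia stays
#' positive definite; when a probe configuration is supplied the positive
#' definiteness is verified there and a nonphysical-model error raised
#' otherwise (a modifier at or below minus the effective mass is never
#' physical).
#'
#' @param params linkage parameters.
#' @param m_hat mass modifier (kg).
#' @param q_probe optional joint configuration at which to verify that the
#'   augmented inertia is positive definite.
#' @return a \code{linkage_params} object.
#' @export
augment_model <- function(params, m_hat, q_probe = NULL) {
  out <- params
  out$endpoint_mass <- params$endpoint_mass + m_hat
  if (!is.null(q_probe)) {
    ev <- eigen(inertia_matrix_impl(out, q_probe), symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0)
      stop(sprintf(
        "nonphysical model: m_hat = %.3f kg drives the inertia indefinite",
        m_hat))
  }
  out
}

#' Predict a blind reach under a mass modifier
#'
#' Plans a minimum-jerk reach, computes inverse-dynamics torques on the
#' mass-augmented model, replays them open-loop (feedforward only, no
#' stopping controller) on the true model, and measures the endpoint error.
#' Extent error is the signed error along the start-to-target direction
#' (positive = overshoot, hypermetria); lateral error is the orthogonal
#' component. \code{extent_error_peak} reads the extent at the trajectory's
#' maximal excursion instead of at the end of the planned duration.
#'
#' @param params true linkage parameters.
#' @param m_hat mass modifier (kg) used for planning.
#' @param spec a \code{\link{reach_spec}}.
#' @param rtol forward-integration tolerance.
#' @return object of class \code{reach_outcome}: list with \code{endpoint},
#'   \code{extent_error}, \code{lateral_error}, \code{extent_error_peak} and
#'   the simulated \code{trajectory} (endpoint path).
#' @export
predict_reach <- function(params, m_hat, spec, rtol = 1e-8) {
  plan <- plan_joint_trajectory(params, spec)
  planning_model <- augment_model(params, m_hat, q_probe = plan$q[1, ])
  # refuse to plan with a non-positive perceived mass along the reach
  dir <- (spec$target - spec$start) / spec$distance
  mid <- nrow(plan$q) %/% 2 + 1L
  m_eff <- min(
    effective_mass(planning_model, plan$q[1, ], atan2(dir[2], dir[1])),
    effective_mass(planning_model, plan$q[mid, ], atan2(dir[2], dir[1])))
  if (m_eff <= 0) stop("nonphysical model: perceived effective mass <= 0")
  torques <- inverse_dynamics(planning_model, plan)
  sim <- forward_simulate(params, torques, q0 = plan$q[1, ],
                          qdot0 = c(0, 0), rtol = rtol)
  endpoint <- sim$x[nrow(sim$x), ]
  extent <- drop((endpoint - spec$target) %*% dir)
  lateral <- drop((endpoint - spec$target) %*% c(-dir[2], dir[1]))
  excursion <- (sim$x[, 1] - spec$start[1]) * dir[1] +
    (sim$x[, 2] - spec$start[2]) * dir[2]
  structure(list(endpoint = endpoint,
                 extent_error = extent,
                 lateral_error = lateral,
                 extent_error_peak = max(excursion) - spec$distance,
                 trajectory = sim$x),
            class = "reach_outcome")
}

#' Reach battery over a target set
#'
#' Runs \code{\link{predict_reach}} for each spec; failures are reported and
#' the battery continues.
#'
#' @param params true linkage parameters.
#' @param m_hat mass modifier (kg).
#' @param specs list of \code{\link{reach_spec}} objects.
#' @return data.frame with one row per target: \code{target_id},
#'   \code{extent_error_m}, \code{lateral_error_m}, \code{extent_error_peak_m},
#'   \code{failed}.
#' @export
reach_battery <- function(params, m_hat, specs) {
  rows <- lapply(seq_along(specs), function(i) {
    out <- tryCatch(predict_reach(params, m_hat, specs[[i]]),
                    error = function(e) e)
    if (inherits(out, "error")) {
      warning(sprintf("reach %d failed: %s", i, conditionMessage(out)))
      data.frame(target_id = i, extent_error_m = NA_real_,
                 lateral_error_m = NA_real_, extent_error_peak_m = NA_real_,
                 failed = TRUE)
    } else {
      data.frame(target_id = i, extent_error_m = out$extent_error,
                 lateral_error_m = out$lateral_error,
                 extent_error_peak_m = out$extent_error_peak,
                 failed = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Standard three-target fan of reach specs
#'
#' Three targets 0.14 m from the start, separated by 45 degrees and centred on
#' the frontal (+y) direction, as in the reaching blocks of the study
#' protocol.
#'
#' @param start numeric(2) starting position (m).
#' @param distance target distance (m).
#' @param duration movement time (s).
#' @return list of three \code{\link{reach_spec}} objects.
#' @export
target_fan <- function(start, distance = 0.14, duration = 0.6) {
  lapply(c(pi / 4, pi / 2, 3 * pi / 4), function(a) {
    reach_spec(start, start + distance * c(cos(a), sin(a)), duration)
  })
}
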