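# Euler-Lagrange dynamics of the five-bar linkage in the two actuated
# coordinates, with passive joints eliminated through the loop closure.
# Horizontal plane: no gravity term anywhere.

# Per-link COM velocity maps G_i (2x2, v_com = G_i %*% q_dot) and angular rate
# rows, assembled into the generalized inertia matrix
#   M(q) = sum_i m_i G_i' G_i + I_i w_i' w_i + m_e J' J
inertia_matrix_impl <- function(params, q, rates = NULL) {
  if (is.null(rates)) rates <- five_bar_rates(params, q)
  l <- params$proximal_lengths
  r <- params$link_com_offsets
  m <- params$link_masses
  Iz <- params$link_inertias
  Phi <- rates$Phi
  M <- matrix(0, 2, 2)
  # proximal links rotate with their own actuated angle only
  M[1, 1] <- m[1] * r[1]^2 + Iz[1]
  M[2, 2] <- m[2] * r[2]^2 + Iz[2]
  G3 <- cbind(l[1] * rates$u1, c(0, 0)) + outer(r[3] * rates$w1, Phi[1, ])
  G4 <- cbind(c(0, 0), l[2] * rates$u2) + outer(r[4] * rates$w2, Phi[2, ])
  M <- M + m[3] * crossprod(G3) + Iz[3] * tcrossprod(Phi[1, ]) +
    m[4] * crossprod(G4) + Iz[4] * tcrossprod(Phi[2, ]) +
    params$endpoint_mass * crossprod(rates$J)
  (M + t(M)) / 2
}

#' Generalized inertia matrix M(q)
#'
#' Symmetric positive-definite 2x2 inertia of the five-bar linkage in the
#' actuated-joint coordinates, with the passive distal joints eliminated
#' through the loop-closure constraint.
#'
#' @inheritParams forward_kinematics
#' @return 2x2 numeric matrix.
#' @export
inertia_matrix <- function(params, q) {
  inertia_matrix_impl(params, q)
}

# dM/dq_k by central differences (M is smooth away from singularities).
inertia_gradient <- function(params, q, h = 1e-6) {
  g <- array(0, c(2, 2, 2))
  for (k in 1:2) {
    dq <- c(0, 0); dq[k] <- h
    g[, , k] <- (inertia_matrix_impl(params, q + dq) -
                   inertia_matrix_impl(params, q - dq)) / (2 * h)
  }
  g
}

#' Coriolis/centripetal matrix C(q, qdot)
#'
#' Christoffel-symbol construction from the configuration gradient of M(q),
#' so that \code{Mdot - 2 C} is skew-symmetric in the quadratic form sense.
#'
#' @inheritParams forward_kinematics
#' @param qdot numeric(2), joint angular velocities (rad/s).
#' @return 2x2 numeric matrix.
#' @export
coriolis_matrix <- function(params, q, qdot) {
  g <- inertia_gradient(params, q)
  C <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    cij <- 0
    for (k in 1:2)
      cij <- cij + 0.5 * (g[i, j, k] + g[i, k, j] - g[j, k, i]) * qdot[k]
    C[i, j] <- cij
  }
  C
}

#' Direction-dependent effective endpoint mass
#'
#' The scalar inertia felt at the handle for motion in a given direction: the
#' projection of the generalized inertia matrix through the inverse Jacobian
#' onto the unit velocity vector, so that the kinetic energy of the linkage
#' equals that of an equivalent point mass moving at the handle.
#'
#' @inheritParams forward_kinematics
#' @param theta_dir direction of instantaneous motion, CCW from +x (rad).
#'   Interpreted modulo pi: the projection is a quadratic form.
#' @return effective mass (kg), strictly positive.
#' @export
effective_mass <- function(params, q, theta_dir) {
  rates <- five_bar_rates(params, q)
  J <- rates$J
  cn <- kappa(J, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf("singular configuration: Jacobian condition number %.3g", cn))
  M <- inertia_matrix_impl(params, q, rates)
  w <- solve(J, unit_vec(theta_dir))
  drop(t(w) %*% M %*% w)
}

#' Polar profile of the effective endpoint mass
#'
#' Effective mass sampled on a uniform angular grid at a fixed configuration,
#' suitable for polar plotting (the anisotropy maps of the manipulandum).
#'
#' @inheritParams forward_kinematics
#' @param n_directions number of directions on \code{[0, 2*pi)}; at least 4.
#' @return data.frame with columns \code{angle_rad}, \code{mass_kg}.
#' @export
effective_mass_polar <- function(params, q, n_directions = 72) {
  if (n_directions < 4) stop("n_directions must be at least 4")
  ang <- seq(0, 2 * pi, length.out = n_directions + 1)[seq_len(n_directions)]
  rates <- five_bar_rates(params, q)
  M <- inertia_matrix_impl(params, q, rates)
  A <- t(solve(rates$J)) %*% M %*% solve(rates$J)
  mass <- vapply(ang, function(a) {
    u <- unit_vec(a)
    drop(t(u) %*% A %*% u)
  }, numeric(1))
  data.frame(angle_rad = ang, mass_kg = mass)
}

#' Inverse dynamics along a joint trajectory
#'
#' Computes the feedforward generalized joint forces
#' \code{u = M(q) qddot + C(q, qdot) qdot} sample by sample (no gravity:
#' horizontal plane). Velocities/accelerations are taken from the trajectory
#' when present, otherwise by central differences on the sampling grid.
#'
#' @inheritParams forward_kinematics
#' @param traj list with \code{t} (uniform time stamps, s), \code{q} (n x 2
#'   matrix), and optionally \code{qdot}, \code{qddot} (n x 2).
#' @return list with \code{t} and \code{u} (n x 2 torque matrix, N m).
#' @export
inverse_dynamics <- function(params, traj) {
  t <- traj$t
  q <- traj$q
  n <- length(t)
  if (n < 3) stop("trajectory too short for inverse dynamics")
  dt <- t[2] - t[1]
  central_diff <- function(x) {
    d <- x
    d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) / (2 * dt)
    d[1, ] <- (x[2, ] - x[1, ]) / dt
    d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
    d
  }
  qdot <- if (!is.null(traj$qdot)) traj$qdot else central_diff(q)
  qddot <- if (!is.null(traj$qddot)) traj$qddot else central_diff(qdot)
  u <- matrix(0, n, 2)
  bad <- integer(0)
  for (i in seq_len(n)) {
    ui <- tryCatch({
      M <- inertia_matrix_impl(params, q[i, ])
      C <- coriolis_matrix(params, q[i, ], qdot[i, ])
      drop(M %*% qddot[i, ] + C %*% qdot[i, ])
    }, error = function(e) NULL)
    if (is.null(ui)) bad <- c(bad, i) else u[i, ] <- ui
  }
  if (length(bad))
    stop("singular configurations along the path at samples: ",
         paste(utils::head(bad, 10), collapse = ", "))
  list(t = t, u = u)
}

#' Forward (open-loop) simulation under a torque series
#'
#' Integrates \code{qddot = M(q)^{-1} (u - C(q,qdot) qdot)} over the torque
#' horizon with an adaptive Runge-Kutta scheme and returns joint and endpoint
#' trajectories resampled on the 200 Hz recording grid of the torque series.
#'
#' @inheritParams forward_kinematics
#' @param torques list with \code{t} (uniform stamps) and \code{u} (n x 2).
#' @param q0 numeric(2) initial joint angles (rad).
#' @param qdot0 numeric(2) initial joint velocities (rad/s).
#' @param rtol relative integration tolerance.
#' @return list with \code{t}, \code{q}, \code{qdot} (n x 2 each) and \code{x}
#'   (n x 2 endpoint positions).
#' @export
forward_simulate <- function(params, torques, q0, qdot0 = c(0, 0),
                             rtol = 1e-8) {
  t <- torques$t
  if (any(!is.finite(torques$u))) stop("torque series must be finite")
  u1f <- stats::approxfun(t, torques$u[, 1], rule = 2)
  u2f <- stats::approxfun(t, torques$u[, 2], rule = 2)
  rhs <- function(tt, y, parms) {
    q <- y[1:2]; qd <- y[3:4]
    M <- inertia_matrix_impl(params, q)
    C <- coriolis_matrix(params, q, qd)
    qdd <- solve(M, c(u1f(tt), u2f(tt)) - drop(C %*% qd))
    list(c(qd, qdd))
  }
  sol <- deSolve::ode(y = c(q0, qdot0), times = t, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = rtol * 1e-2)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(t))
    stop("integration failure in forward simulation")
  q <- unname(sol[, 2:3, drop = FALSE])
  qd <- unname(sol[, 4:5, drop = FALSE])
  x <- t(apply(q, 1, function(qi) forward_kinematics(params, qi)))
  list(t = t, q = q, qdot = qd, x = x)
}

# Kinetic energy of the full linkage at a state; used by tests and passivity
# checks.
kinetic_energy <- function(params, q, qdot) {
  M <- inertia_matrix_impl(params, q)
  0.5 * drop(t(qdot) %*% M %*% qdot)
}
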