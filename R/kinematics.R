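# Closed-form kinematics of the planar five-bar linkage.
#
# Generalized coordinates are the two actuated base angles q = (q1, q2),
# measured CCW from +x. Base joints: A1 = (-d/2, 0), A2 = (+d/2, 0). The
# passive distal angles follow from the loop-closure constraint. The working
# mode is fixed elbow-out: the handle is the circle-intersection branch away
# from the base line, and each elbow bulges outward from its base-to-handle
# chord. Branches are never switched mid-trajectory.

unit_vec <- function(a) c(cos(a), sin(a))
perp_vec <- function(a) c(-sin(a), cos(a))   # d/da of unit_vec

base_joints <- function(params) {
  d <- params$base_separation / 2
  list(A1 = c(-d, 0), A2 = c(d, 0))
}

# Full mechanism pose: elbow positions, passive angles, handle position.
# Errors out when the loop closure has no real solution.
five_bar_pose <- function(params, q) {
  b <- base_joints(params)
  l <- params$proximal_lengths
  s <- params$distal_lengths
  E1 <- b$A1 + l[1] * unit_vec(q[1])
  E2 <- b$A2 + l[2] * unit_vec(q[2])
  dv <- E2 - E1
  D <- sqrt(sum(dv^2))
  if (D < 1e-12)
    stop("closure failure: coincident elbow joints")
  a <- (s[1]^2 - s[2]^2 + D^2) / (2 * D)
  h2 <- s[1]^2 - a^2
  if (h2 <= 0)
    stop(sprintf("closure failure: distal links cannot meet (gap %.4g m)",
                 sqrt(max(h2 * -1, 0))))
  h <- sqrt(h2)
  mid <- E1 + a * dv / D
  # elbow-out branch: handle on the +perp side of the elbow-to-elbow chord
  P <- mid + h * c(-dv[2], dv[1]) / D
  phi1 <- atan2(P[2] - E1[2], P[1] - E1[1])
  phi2 <- atan2(P[2] - E2[2], P[1] - E2[1])
  list(P = P, E1 = E1, E2 = E2, phi = c(phi1, phi2))
}

#' Forward kinematics of the five-bar linkage
#'
#' Maps actuated joint angles to the planar handle position on the fixed
#' elbow-out working mode.
#'
#' @param params a \code{\link{linkage_params}} object.
#' @param q numeric(2), actuated base joint angles (rad, CCW from +x).
#' @return numeric(2) handle position (m).
#' @export
forward_kinematics <- function(params, q) {
  five_bar_pose(params, q)$P
}

#' Inverse kinematics of the five-bar linkage
#'
#' Returns the actuated joint angles that place the handle at \code{x}, on the
#' elbow-out branch (left elbow to the left of its base-to-handle chord, right
#' elbow to the right).
#'
#' @param params a \code{\link{linkage_params}} object.
#' @param x numeric(2) handle position (m).
#' @return numeric(2) joint angles (rad).
#' @export
inverse_kinematics <- function(params, x) {
  b <- base_joints(params)
  l <- params$proximal_lengths
  s <- params$distal_lengths
  q <- numeric(2)
  for (arm in 1:2) {
    A <- if (arm == 1) b$A1 else b$A2
    dv <- x - A
    D <- sqrt(sum(dv^2))
    if (D >= l[arm] + s[arm] || D <= abs(l[arm] - s[arm]))
      stop(sprintf("workspace error: handle at distance %.3f m from base %d (limits %.3f-%.3f m)",
                   D, arm, abs(l[arm] - s[arm]), l[arm] + s[arm]))
    a <- (l[arm]^2 - s[arm]^2 + D^2) / (2 * D)
    h <- sqrt(l[arm]^2 - a^2)
    mid <- A + a * dv / D
    pp <- c(-dv[2], dv[1]) / D
    # elbow-out: left arm elbow CCW of the chord, right arm elbow CW
    E <- if (arm == 1) mid + h * pp else mid - h * pp
    q[arm] <- atan2(E[2] - A[2], E[1] - A[1])
  }
  q
}

# Velocity-level closure: passive angle rates phi_dot = Phi %*% q_dot and the
# 2x2 endpoint Jacobian, from one linear solve of the differentiated loop
# equation. Returns pose pieces too, so dynamics can reuse them.
five_bar_rates <- function(params, q, pose = NULL) {
  if (is.null(pose)) pose <- five_bar_pose(params, q)
  l <- params$proximal_lengths
  s <- params$distal_lengths
  u1 <- perp_vec(q[1]); u2 <- perp_vec(q[2])
  w1 <- perp_vec(pose$phi[1]); w2 <- perp_vec(pose$phi[2])
  # closure: l1 q1. u1 + s1 phi1. w1 = l2 q2. u2 + s2 phi2. w2
  B <- cbind(s[1] * w1, -s[2] * w2)
  detB <- B[1, 1] * B[2, 2] - B[1, 2] * B[2, 1]
  if (abs(detB) < 1e-10 * s[1] * s[2])
    stop(sprintf("singular configuration: distal links aligned (det %.3g)", detB))
  Dm <- cbind(-l[1] * u1, l[2] * u2)
  Phi <- solve(B, Dm)
  J <- cbind(l[1] * u1, c(0, 0)) + outer(s[1] * w1, Phi[1, ])
  list(pose = pose, Phi = Phi, J = J, u1 = u1, u2 = u2, w1 = w1, w2 = w2)
}

#' Endpoint Jacobian of the five-bar linkage
#'
#' The 2x2 matrix mapping actuated joint rates to handle velocity. A
#' singularity error (with the determinant reported) is raised when the distal
#' links align or the map becomes ill-conditioned.
#'
#' @inheritParams forward_kinematics
#' @return 2x2 numeric matrix.
#' @export
jacobian <- function(params, q) {
  J <- five_bar_rates(params, q)$J
  cn <- kappa(J, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop(sprintf("singular configuration: Jacobian condition number %.3g", cn))
  J
}
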