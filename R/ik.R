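#' Damped least-squares inverse kinematics
#'
#' Iterative differential IK for the planar arm: at each step the joint
#' update solves (J J' + lambda^2 I) dx = residual and steps along
#' J' times the solution. With three joints and a planar goal the task is
#' redundant; the damped step is the minimum-norm one, so solutions stay
#' close to the seed posture.
#'
#' @param target Goal point \code{c(x, y)}.
#' @param seed Starting posture for the iteration.
#' @param arm An \code{\link{arm_parameters}} object.
#' @param lambda Damping factor.
#' @param tol Convergence tolerance on the endpoint residual.
#' @param max_iter Iteration cap.
#' @return List with \code{posture}, \code{endpoint}, \code{error} and
#'   logical \code{converged}.
#' @export
dls_ik <- function(target, seed, arm = arm_parameters(), lambda = 0.1,
                   tol = 1e-8, max_iter = 200) {
  q <- check_posture(seed)
  for (i in seq_len(max_iter)) {
    r <- target - forward_kinematics(q, arm)
    if (sqrt(sum(r^2)) < tol) break
    J <- arm_jacobian(q, arm)
    q <- q + drop(t(J) %*% solve(J %*% t(J) + lambda^2 * diag(2), r))
  }
  err <- sqrt(sum((target - forward_kinematics(q, arm))^2))
  list(posture = q, endpoint = forward_kinematics(q, arm), error = err,
       converged = err < 1e-6)
}

#' Inverse kinematics constrained to a plane in motor space
#'
#' Solves for a posture of the form \code{seed + basis \%*\% z} reaching a
#' goal point, by damped Gauss-Newton in the two plane coordinates z. The
#' plane Jacobian is \code{arm_jacobian(q) \%*\% basis} (2 x 2). Used to
#' plant two-dimensional synergy solutions with known ground truth.
#'
#' @param target Goal point \code{c(x, y)}.
#' @param seed Posture the plane passes through.
#' @param basis Orthonormal 3 x 2 matrix spanning the plane.
#' @inheritParams dls_ik
#' @param z0 Initial plane coordinates for the iteration.
#' @return As \code{\link{dls_ik}}, plus the plane coordinates \code{z}.
#' @export
planar_ik <- function(target, seed, basis, arm = arm_parameters(),
                      lambda = 0.05, tol = 1e-10, max_iter = 300,
                      z0 = c(0, 0)) {
  seed <- check_posture(seed)
  z <- z0
  for (i in seq_len(max_iter)) {
    q <- seed + drop(basis %*% z)
    r <- target - forward_kinematics(q, arm)
    if (sqrt(sum(r^2)) < tol) break
    Jp <- arm_jacobian(q, arm) %*% basis
    z <- z + drop(t(Jp) %*% solve(Jp %*% t(Jp) + lambda^2 * diag(2), r))
  }
  q <- seed + drop(basis %*% z)
  err <- sqrt(sum((target - forward_kinematics(q, arm))^2))
  list(posture = q, endpoint = forward_kinematics(q, arm), z = z,
       error = err, converged = err < 1e-6)
}

# null-space projector of the task Jacobian at posture q:
# directions that do not move the endpoint to first order
null_space_projector <- function(q, arm) {
  J <- arm_jacobian(q, arm)
  Jp <- t(J) %*% solve(J %*% t(J) + 1e-10 * diag(2))
  diag(3) - Jp %*% J
}
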