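#' Arm geometry parameters
#'
#' Segment lengths of the three-segment planar kinematic chain used
#' throughout the package. Lengths are in arm units; the default arm has
#' total length 1, so the reachable workspace is the unit disc.
#'
#' @param l1,l2,l3 Segment lengths (> 0). Defaults are the study arm:
#'   0.55, 0.225, 0.225.
#' @return An object of class \code{"arm_parameters"}: a named numeric
#'   vector of the three lengths.
#' @examples
#' arm <- arm_parameters()
#' sum(arm)  # total reach = 1
#' @export
arm_parameters <- function(l1 = 0.55, l2 = 0.225, l3 = 0.225) {
  l <- c(l1 = l1, l2 = l2, l3 = l3)
  if (!all(is.finite(l)) || any(l <= 0))
    stop("segment lengths must be finite and > 0")
  structure(l, class = "arm_parameters")
}

check_posture <- function(q) {
  if (length(q) != 3L || !is.numeric(q) || !all(is.finite(q)))
    stop("invalid posture: need 3 finite joint angles")
  unname(as.numeric(q))
}

#' Forward kinematics of the planar three-joint arm
#'
#' Maps a posture (three joint angles, radians) to the planar reach
#' endpoint: x = sum_k l_k cos(q_1 + ... + q_k), and likewise with sin for
#' y. The map is 2*pi-periodic in every joint; no joint limits are applied,
#' so unfolded angles outside [0, 2*pi) are valid input.
#'
#' @param posture Numeric vector of three joint angles (radians), or a
#'   matrix with three columns (one posture per row).
#' @param arm An \code{\link{arm_parameters}} object.
#' @return For a single posture, a numeric vector \code{c(x, y)}; for a
#'   matrix input, a two-column matrix of endpoints.
#' @examples
#' forward_kinematics(c(3 * pi / 4, 1.99, pi))  # approx (-0.39, 0.39)
#' @export
forward_kinematics <- function(posture, arm = arm_parameters()) {
  if (is.matrix(posture)) {
    if (ncol(posture) != 3L || !all(is.finite(posture)))
      stop("invalid posture: need 3 finite joint angles per row")
    a1 <- posture[, 1L]
    a2 <- a1 + posture[, 2L]
    a3 <- a2 + posture[, 3L]
    return(cbind(
      x = arm[1L] * cos(a1) + arm[2L] * cos(a2) + arm[3L] * cos(a3),
      y = arm[1L] * sin(a1) + arm[2L] * sin(a2) + arm[3L] * sin(a3)
    ))
  }
  q <- check_posture(posture)
  a <- cumsum(q)
  c(x = sum(arm * cos(a)), y = sum(arm * sin(a)))
}

#' Jacobian of the forward kinematics
#'
#' The 2 x 3 matrix of partial derivatives of the endpoint with respect to
#' the joint angles. Column i is the instantaneous endpoint velocity per
#' unit angular velocity of joint i; its norm is the distance from joint i
#' to the endpoint (so the third column always has norm l3).
#'
#' @inheritParams forward_kinematics
#' @return A 2 x 3 numeric matrix (rows: x, y; columns: q1, q2, q3).
#' @export
arm_jacobian <- function(posture, arm = arm_parameters()) {
  q <- check_posture(posture)
  a <- cumsum(q)
  sx <- -arm * sin(a)
  sy <- arm * cos(a)
  # joint i moves all segments k >= i
  rbind(rev(cumsum(rev(sx))), rev(cumsum(rev(sy))))
}

polar_xy <- function(r, theta) cbind(x = r * cos(theta), y = r * sin(theta))

#' Task geometry: home postures, baseline posture and target arrays
#'
#' Builds the reaching task shared by simulated agents and (synthetic)
#' human sessions: two home postures H1 and H2 that reach the same goal
#' point, the baseline posture q* midway between them in motor space, a
#' regular polar array of 16 training targets in the upper quarter segment
#' of the workspace, and 9 test targets (5 interior, 4 exterior).
#'
#' The source text places two interior test targets at polar angle 4/3*pi,
#' outside the trained quarter segment, while describing them as lying
#' within the training array. The \code{"corrected"} variant (default)
#' reads this as 1/3*pi; \code{"printed"} keeps the verbatim values for
#' audit purposes.
#'
#' @param variant \code{"corrected"} or \code{"printed"} (see Details).
#' @param arm An \code{\link{arm_parameters}} object.
#' @return An object of class \code{"task_geometry"}: a list with elements
#'   \code{arm}, \code{home_H1}, \code{home_H2}, \code{baseline_q_star},
#'   \code{training_targets} (16 x 2), \code{test_targets} (9 x 2),
#'   \code{training_polar}, \code{test_polar}, \code{variant}.
#' @examples
#' geo <- build_task_geometry()
#' nrow(geo$training_targets)  # 16
#' @export
build_task_geometry <- function(variant = c("corrected", "printed"),
                                arm = arm_parameters()) {
  variant <- match.arg(variant)
  radii <- c(0.25, 0.45, 0.65, 0.85)
  angles <- c(1 / 4, 5 / 12, 7 / 12, 3 / 4) * pi
  gr <- expand.grid(r = radii, theta = angles)
  interior_angle <- if (variant == "corrected") 1 / 3 else 4 / 3
  test_polar <- rbind(
    c(0.35, 2 / 3), c(0.75, 2 / 3), c(0.55, 1 / 2),
    c(0.35, interior_angle), c(0.75, interior_angle),
    c(0.55, 1 / 6), c(0.15, 1 / 2), c(0.95, 1 / 2), c(0.55, 5 / 6)
  )
  colnames(test_polar) <- c("r", "theta_pi")
  structure(list(
    arm = arm,
    home_H1 = c(3 * pi / 4, 1.99, pi),
    home_H2 = c(1.51, 1.99, 0),
    baseline_q_star = c(1.93, 1.99, pi / 2),
    training_targets = polar_xy(gr$r, gr$theta),
    test_targets = polar_xy(test_polar[, 1], test_polar[, 2] * pi),
    training_polar = cbind(r = gr$r, theta = gr$theta),
    test_polar = cbind(r = test_polar[, 1], theta = test_polar[, 2] * pi),
    variant = variant
  ), class = "task_geometry")
}

#' @export
print.task_geometry <- function(x, ...) {
  cat("Planar 3-DoF reaching task (", x$variant, " test-target variant)\n",
      sep = "")
  cat("  segment lengths:", paste(format(unclass(x$arm)), collapse = ", "), "\n")
  cat("  H1 =", paste(round(x$home_H1, 3), collapse = ", "),
      " -> ", paste(round(forward_kinematics(x$home_H1, x$arm), 2),
                    collapse = ", "), "\n")
  cat("  H2 =", paste(round(x$home_H2, 3), collapse = ", "),
      " -> ", paste(round(forward_kinematics(x$home_H2, x$arm), 2),
                    collapse = ", "), "\n")
  cat("  ", nrow(x$training_targets), "training targets,",
      nrow(x$test_targets), "test targets\n")
  invisible(x)
}

#' Redundancy map of the goal space
#'
#' Quantifies motor redundancy as the number of joint configurations that
#' reach each region of the goal plane. Postures are sampled uniformly
#' from [0, 2*pi)^3 (Monte-Carlo, the default) or enumerated on a regular
#' per-joint grid, pushed through the forward kinematics, and binned on a
#' Cartesian grid over [-1, 1]^2. Redundancy is strongly concentrated
#' towards the origin.
#'
#' @param cells Number of grid cells per axis.
#' @param n_samples Number of posture draws (Monte-Carlo mode).
#' @param step Optional per-joint angular step; when given, postures are
#'   enumerated on \code{seq(0, 2*pi - step, by = step)^3} instead of
#'   sampled.
#' @param normalize Divide counts by the total number of postures.
#' @param arm An \code{\link{arm_parameters}} object.
#' @return An object of class \code{"redundancy_grid"}: list with
#'   \code{counts} (cells x cells matrix, x indexing rows), \code{edges},
#'   \code{n_total} and \code{n_in_grid}.
#' @export
redundancy_map <- function(cells = 20, n_samples = 1e6, step = NULL,
                           normalize = FALSE, arm = arm_parameters()) {
  if (cells < 1) stop("empty grid")
  if (is.null(step)) {
    if (n_samples < 1) stop("n_samples must be >= 1")
    Q <- matrix(stats::runif(3 * n_samples, 0, 2 * pi), ncol = 3)
  } else {
    g <- seq(0, 2 * pi - step, by = step)
    Q <- as.matrix(expand.grid(q1 = g, q2 = g, q3 = g))
  }
  xy <- forward_kinematics(Q, arm)
  edges <- seq(-1, 1, length.out = cells + 1)
  ix <- findInterval(xy[, 1], edges, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2], edges, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= cells & iy >= 1 & iy <= cells
  counts <- matrix(0, cells, cells)
  tab <- table(factor(ix[ok], levels = 1:cells), factor(iy[ok], levels = 1:cells))
  counts[] <- as.numeric(tab)
  out <- list(counts = if (normalize) counts / nrow(Q) else counts,
              edges = edges, n_total = nrow(Q), n_in_grid = sum(ok))
  class(out) <- "redundancy_grid"
  out
}

#' Baseline reach error of a fixed posture
#'
#' Mean Euclidean distance from the endpoint of a single posture to a set
#' of targets: the error an agent or participant would make by never
#' moving. Both home postures share an endpoint, so they share a baseline.
#'
#' @param posture Joint-angle vector.
#' @param targets Two-column matrix of goal points.
#' @param arm An \code{\link{arm_parameters}} object.
#' @return Mean distance (scalar).
#' @export
baseline_error <- function(posture, targets, arm = arm_parameters()) {
  targets <- rbind(targets)
  if (nrow(targets) < 1) stop("empty target list")
  p <- forward_kinematics(posture, arm)
  mean(sqrt((targets[, 1] - p[1])^2 + (targets[, 2] - p[2])^2))
}
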