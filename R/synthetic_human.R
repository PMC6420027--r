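#' Parameters of the synthetic human-session generator
#'
#' The generator produces sessions with the statistical signatures the
#' analysis pipeline assumes of human learners — high early posture
#' variability that decreases with practice, a two-dimensional synergy
#' plane that consolidates, a solution location biased towards the home
#' posture, and occasional missing trials — with a fully known ground
#' truth (the planted plane, bias and noise schedules), so that every
#' analysis stage can be validated by parameter recovery. It is a
#' parametric model of \emph{intended} test postures plus motor noise,
#' not a trial-by-trial learning simulation.
#'
#' Schedules are per-block vectors of length \code{n_blocks}; scalar
#' inputs are recycled, two-element inputs are interpolated linearly
#' across blocks.
#'
#' @param condition \code{"H1"} or \code{"H2"}.
#' @param mapping Signed finger-mapping triple.
#' @param n_blocks Number of training/test blocks (default 24).
#' @param lambda Home-bias schedule in [0, 1]: the block's central
#'   posture is H + lambda * (q* - H), so 0 sits at the condition's home
#'   posture and 1 at the baseline posture.
#' @param in_plane_sd In-plane motor-noise schedule (rad); default decays
#'   0.6 to 0.2 across blocks.
#' @param out_of_plane_sd Out-of-plane noise schedule (rad); default
#'   decays 0.3 to 0.05, so the third synergy's share of variance shrinks
#'   with practice.
#' @param plane_basis Orthonormal 3 x 2 basis of the planted synergy
#'   plane, or \code{NULL} for a condition-adapted default spanned by the
#'   q1 axis (whole-arm rotation, controlling reach angle) and a radius
#'   synergy (0, cos phi, sin phi) with phi = 60 deg for H1 (q3-dominant)
#'   and phi = 30 deg for H2 (q2-dominant); these planes reach every
#'   target from the respective central postures with a compact solution
#'   sheet.
#' @param rotation_deg Per-block rotation schedule (degrees) applied to
#'   the plane within motor space around its normal-orthogonal pivot;
#'   default 0 (fixed plane).
#' @param missing_prob Per-trial probability that the motion sensor fails
#'   and the trial is discarded (default 0.014).
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @return List of class \code{"human_params"}.
#' @export
human_params <- function(condition = c("H1", "H2"),
                         mapping = c(1L, 2L, 3L),
                         n_blocks = 24,
                         lambda = 0.3,
                         in_plane_sd = c(0.6, 0.2),
                         out_of_plane_sd = c(0.3, 0.05),
                         plane_basis = NULL,
                         rotation_deg = 0,
                         missing_prob = 0.014,
                         geometry = build_task_geometry()) {
  condition <- match.arg(condition)
  sched <- function(x) {
    if (length(x) == n_blocks) return(x)
    if (length(x) == 1) return(rep(x, n_blocks))
    if (length(x) == 2) return(seq(x[1], x[2], length.out = n_blocks))
    stop("schedule must have length 1, 2 or n_blocks")
  }
  out <- list(condition = condition, mapping = mapping, n_blocks = n_blocks,
              lambda = sched(lambda),
              in_plane_sd = sched(in_plane_sd),
              out_of_plane_sd = sched(out_of_plane_sd),
              plane_basis = plane_basis,
              rotation_deg = sched(rotation_deg),
              missing_prob = missing_prob,
              geometry = geometry)
  stopifnot(all(out$lambda >= 0 & out$lambda <= 1),
            all(out$in_plane_sd >= 0), all(out$out_of_plane_sd >= 0),
            missing_prob >= 0, missing_prob < 1)
  class(out) <- "human_params"
  out
}

# rotate an orthonormal 3x2 basis by angle (rad) within the plane spanned
# by its first axis and the plane normal: tilts the plane, keeping rank 2
rotate_basis <- function(basis, angle) {
  if (angle == 0) return(basis)
  n <- pracma_cross(basis[, 1], basis[, 2])
  b1 <- cos(angle) * basis[, 1] + sin(angle) * n
  cbind(b1, basis[, 2])
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Plant an expert solution for one block
#'
#' Computes, for each target, an "expert" posture lying on the planted
#' synergy plane through the block's central posture
#' c_b = H + lambda_b (q* - H): damped Gauss-Newton inverse kinematics in
#' the two plane coordinates (see \code{\link{planar_ik}}), seeded at
#' c_b. Targets the plane cannot reach within 0.01 are flagged.
#'
#' @param params A \code{\link{human_params}} object.
#' @param block Block number (selects the schedule entries).
#' @param targets Matrix of goal points; default the nine test targets.
#' @return List: \code{postures} (targets x 3), \code{flagged} (logical),
#'   \code{centre} (the seed posture c_b), \code{basis} (the block's
#'   plane basis).
#' @export
plant_solution <- function(params, block = 1, targets = NULL) {
  geo <- params$geometry
  if (is.null(targets)) targets <- geo$test_targets
  home <- if (params$condition == "H1") geo$home_H1 else geo$home_H2
  centre <- home + params$lambda[block] * (geo$baseline_q_star - home)
  basis <- params$plane_basis
  if (is.null(basis)) {
    # condition-adapted default: q1 (reach angle) plus a radius synergy
    # that is q3-dominant from H1 and q2-dominant from H2 -- the
    # orientations that keep the expert sheet compact from each side
    phi <- if (params$condition == "H1") pi / 3 else pi / 6
    basis <- cbind(c(1, 0, 0), c(0, cos(phi), sin(phi)))
  }
  basis <- rotate_basis(basis, params$rotation_deg[block] * pi / 180)
  P <- matrix(NA_real_, nrow(targets), 3)
  flagged <- logical(nrow(targets))
  starts <- c(list(c(0, 0)),
              unlist(lapply(c(1, 2, 3), function(r)
                lapply(seq(0, 2 * pi - pi / 4, by = pi / 4), function(a)
                  r * c(cos(a), sin(a)))), recursive = FALSE))
  for (i in seq_len(nrow(targets))) {
    best <- NULL
    for (z0 in starts) {
      sol <- planar_ik(targets[i, ], centre, basis, geo$arm, z0 = z0)
      # among converged branches keep the one closest to the centre, so
      # expert postures form one compact sheet rather than mixing branches
      better <- is.null(best) ||
        (sol$error < 1e-8 && best$error >= 1e-8) ||
        (sol$error < 1e-8 && best$error < 1e-8 &&
           sum(sol$z^2) < sum(best$z^2)) ||
        (sol$error >= 1e-8 && best$error >= 1e-8 && sol$error < best$error)
      if (better) best <- sol
    }
    P[i, ] <- best$posture
    flagged[i] <- best$error > 0.01
  }
  list(postures = P, flagged = flagged, centre = centre, basis = basis)
}

#' Generate one synthetic human session
#'
#' For every block, the intended test postures are the planted expert
#' solutions; executed postures add in-plane Gaussian motor noise
#' (expressed in the block's plane basis) and out-of-plane noise along
#' the plane normal, with standard deviations from the schedules.
#' Endpoints follow by forward kinematics; each test trial is
#' independently missing with the configured probability (the sensor
#' fails for the whole trial, so missing trials carry no posture).
#' Training metadata (target order, arrival scores) is schematic.
#'
#' @param params A \code{\link{human_params}} object.
#' @param participant Participant identifier.
#' @param session Session number (1 or 2).
#' @param mapping_id Mapping identifier used for statistical grouping.
#' @return A session record (common session schema, kind
#'   \code{"synthetic_human"}) with a \code{ground_truth} attribute
#'   holding the planted parameters.
#' @export
generate_session <- function(params, participant = 1, session = 1,
                             mapping_id = 1) {
  geo <- params$geometry
  tt <- geo$test_targets
  blocks <- vector("list", params$n_blocks)
  truth <- vector("list", params$n_blocks)
  plan_cache <- list()
  for (b in seq_len(params$n_blocks)) {
    key <- paste(params$lambda[b], params$rotation_deg[b])
    if (is.null(plan_cache[[key]]))
      plan_cache[[key]] <- plant_solution(params, b)
    plan <- plan_cache[[key]]
    n <- pracma_cross(plan$basis[, 1], plan$basis[, 2])
    n <- n / sqrt(sum(n^2))
    z <- matrix(stats::rnorm(2 * nrow(tt), 0, params$in_plane_sd[b]),
                ncol = 2)
    w <- stats::rnorm(nrow(tt), 0, params$out_of_plane_sd[b])
    Q <- plan$postures + z %*% t(plan$basis) + outer(w, n)
    E <- forward_kinematics(Q, geo$arm)
    miss <- stats::runif(nrow(tt)) < params$missing_prob
    test <- data.frame(
      target_x = tt[, 1], target_y = tt[, 2],
      intended_q1 = plan$postures[, 1], intended_q2 = plan$postures[, 2],
      intended_q3 = plan$postures[, 3],
      q1 = Q[, 1], q2 = Q[, 2], q3 = Q[, 3],
      x = E[, 1], y = E[, 2],
      distance = sqrt(rowSums((E - tt)^2)),
      missing = miss)
    test[miss, c("q1", "q2", "q3", "x", "y", "distance")] <- NA_real_
    traj <- training_trajectory(geo)
    blocks[[b]] <- list(
      block = b,
      training = list(target_order = traj$order,
                      arrival_scores = reach_score(
                        pmin(1, abs(stats::rnorm(length(traj$order), 0.15,
                                                 0.1))))),
      test = test)
    truth[[b]] <- list(centre = plan$centre, basis = plan$basis,
                       flagged = plan$flagged)
  }
  rec <- list(schema = session_schema_version(),
              id = sprintf("human-%02d-s%d", participant, session),
              kind = "synthetic_human",
              condition = params$condition,
              mapping = as.integer(params$mapping),
              mapping_id = mapping_id,
              participant = participant,
              seed = NA_integer_,
              n_blocks = params$n_blocks,
              blocks = blocks)
  attr(rec, "ground_truth") <- list(params = params, blocks = truth)
  rec
}

#' Generate a counterbalanced 20-participant synthetic dataset
#'
#' Builds the full experimental design: \code{n_participants}
#' participants, two sessions each (one per condition, starting condition
#' counterbalanced), finger mappings drawn without replacement with each
#' mapping reused once in the other condition by the paired participant.
#'
#' @param n_participants Even number of participants (default 20).
#' @param seed Integer seed for the whole dataset.
#' @param ... Passed to \code{\link{human_params}} (schedules etc.).
#' @return List of class \code{"human_population"}: \code{sessions} (one
#'   record per participant-session, 2 x n_participants in total) and
#'   \code{roster}.
#' @export
generate_population <- function(n_participants = 20, seed = 1L, ...) {
  set.seed(seed)
  roster <- counterbalanced_roster(n_participants)
  sessions <- vector("list", nrow(roster))
  for (i in seq_len(nrow(roster))) {
    row <- roster[i, ]
    p <- human_params(condition = row$condition,
                      mapping = c(row$m1, row$m2, row$m3), ...)
    sessions[[i]] <- generate_session(p, participant = row$participant,
                                      session = row$session,
                                      mapping_id = row$mapping_id)
  }
  structure(list(sessions = sessions, roster = roster, seed = seed),
            class = "human_population")
}

#' @export
print.human_population <- function(x, ...) {
  cat("Synthetic human dataset:", length(x$sessions), "sessions (",
      length(unique(x$roster$participant)), "participants x 2 conditions)\n")
  invisible(x)
}
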