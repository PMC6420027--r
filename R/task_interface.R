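#' All signed finger-to-joint mappings
#'
#' Participants control the three joint angles with three fingers (left
#' index, right index, right middle) under a randomized signed
#' permutation: 6 permutations x 8 sign patterns = 48 mappings. A mapping
#' is stored as a signed triple, e.g. \code{c(-2, 3, -1)}: the first
#' finger controls joint 2 with inverted direction, the second controls
#' joint 3, the third controls joint 1 inverted.
#'
#' @return A 48 x 3 integer matrix, one mapping per row.
#' @export
all_finger_mappings <- function() {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  out <- matrix(0L, 48, 3)
  k <- 0
  for (i in seq_len(nrow(perms))) for (j in seq_len(nrow(signs))) {
    k <- k + 1
    out[k, ] <- as.integer(perms[i, ] * signs[j, ])
  }
  colnames(out) <- c("left_index", "right_index", "right_middle")
  out
}

#' Draw a finger mapping without replacement
#'
#' Uniform draw from the 48 signed permutations, excluding mappings
#' already in use (counterbalancing across sessions).
#'
#' @param already_used Optional matrix of mappings (rows) to exclude.
#' @return A signed integer triple.
#' @export
draw_finger_mapping <- function(already_used = NULL) {
  pool <- all_finger_mappings()
  if (!is.null(already_used)) {
    used <- apply(rbind(already_used), 1, paste, collapse = ",")
    keep <- !(apply(pool, 1, paste, collapse = ",") %in% used)
    pool <- pool[keep, , drop = FALSE]
  }
  if (nrow(pool) == 0) stop("finger-mapping pool exhausted")
  pool[sample.int(nrow(pool), 1), ]
}

#' Convert finger elevations to a posture
#'
#' Each finger's vertical elevation moves its mapped joint away from the
#' baseline posture q* = (1.93, 1.99, pi/2): five centimetres of finger
#' movement correspond to an angle change of pi, with the mapping's sign
#' giving the direction. No wrapping is applied, so large elevations
#' produce unfolded angles.
#'
#' @param elevations_cm Numeric 3-vector of finger elevations (cm), in
#'   finger order (left index, right index, right middle).
#' @param mapping Signed triple from \code{\link{draw_finger_mapping}}.
#' @param baseline Baseline posture (defaults to q*).
#' @return Posture 3-vector.
#' @export
fingers_to_posture <- function(elevations_cm, mapping,
                               baseline = build_task_geometry()$baseline_q_star) {
  stopifnot(length(elevations_cm) == 3, all(is.finite(elevations_cm)))
  q <- baseline
  joint <- abs(mapping)
  q[joint] <- q[joint] + sign(mapping) * (pi / 5) * elevations_cm
  unname(q)
}

#' Convert a posture to finger elevations
#'
#' Exact inverse of \code{\link{fingers_to_posture}}.
#'
#' @inheritParams fingers_to_posture
#' @param posture Posture 3-vector.
#' @return Elevations (cm) in finger order.
#' @export
posture_to_fingers <- function(posture, mapping,
                               baseline = build_task_geometry()$baseline_q_star) {
  posture <- check_posture(posture)
  joint <- abs(mapping)
  unname(sign(mapping) * (5 / pi) * (posture[joint] - baseline[joint]))
}

#' Encode a goal point as an ellipse
#'
#' Goal feedback is displayed as an ellipse: the x coordinate sets the
#' base radius (linear map of [-1, 1] onto [0.66, 3.30] degrees visual
#' angle) and the y coordinate the elongation (linear map onto
#' [-0.5, 0.5]); horizontal radius r(1 - elongation), vertical
#' r(1 + elongation). Coordinates outside [-1, 1] are clipped and the
#' clipping is reported.
#'
#' @param goal Goal point \code{c(x, y)}.
#' @return List of class \code{"ellipse_code"}: \code{r},
#'   \code{elongation}, \code{r_horizontal}, \code{r_vertical},
#'   \code{clipped}.
#' @export
encode_ellipse <- function(goal) {
  clipped <- any(goal < -1 | goal > 1)
  g <- pmin(1, pmax(-1, goal))
  r <- 0.66 + (g[1] + 1) / 2 * (3.30 - 0.66)
  eps <- g[2] / 2
  structure(list(r = r, elongation = eps,
                 r_horizontal = r * (1 - eps), r_vertical = r * (1 + eps),
                 clipped = clipped),
            class = "ellipse_code")
}

#' Trial score
#'
#' score = (max(0, 1 - d))^2 * 100, where d is the goal-space distance
#' between target and reach endpoint. The clamp is applied before
#' squaring so the score is monotone non-increasing in d and zero for
#' d >= 1. \code{printed_literal = TRUE} evaluates the source formula
#' max(0, (1 - d)^2) * 100 verbatim for audits (it rises again for
#' d > 1).
#'
#' @param d Non-negative distance (vectorized).
#' @param printed_literal Use the literal printed formula.
#' @return Score in [0, 100].
#' @export
reach_score <- function(d, printed_literal = FALSE) {
  if (any(d < 0)) stop("distance must be non-negative")
  if (printed_literal) return(pmax(0, (1 - d)^2) * 100)
  pmax(0, 1 - d)^2 * 100
}

#' Timed training trajectory
#'
#' One training block presents the 16 training targets in random order as
#' a continuously deforming target ellipse: each of the 16 segments is a
#' straight goal-space path lasting 5 s, 80 s in total, with a score
#' event at each target arrival.
#'
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @param dt Sampling interval in seconds.
#' @param start Goal point the trajectory starts from; default is the
#'   shared endpoint of the home postures.
#' @return List of class \code{"training_trajectory"}: \code{order}
#'   (target indices), \code{time} (s), \code{path} (goal points sampled
#'   every \code{dt}), \code{arrival_times}, \code{segment_s = 5},
#'   \code{total_s = 80}.
#' @export
training_trajectory <- function(geometry = build_task_geometry(), dt = 0.1,
                                start = NULL) {
  tt <- geometry$training_targets
  if (is.null(start))
    start <- forward_kinematics(geometry$home_H1, geometry$arm)
  ord <- sample.int(nrow(tt))
  seg_s <- 5
  total_s <- seg_s * nrow(tt)
  time <- seq(0, total_s, by = dt)
  pts <- rbind(start, tt[ord, ])  # 16 segments, each ending at a target
  # segment k runs over ((k-1)*5, k*5]; position interpolates pts[k] -> pts[k+1]
  k <- pmin(nrow(tt), pmax(1, ceiling(time / seg_s)))
  frac <- (time - (k - 1) * seg_s) / seg_s
  path <- pts[k, , drop = FALSE] * (1 - frac) +
    pts[k + 1, , drop = FALSE] * frac
  list(order = ord, time = time, path = path,
       arrival_times = seg_s * seq_len(nrow(tt)),
       segment_s = seg_s, total_s = total_s)
}

#' Counterbalanced participant roster
#'
#' Builds the 20-participant design: half start in condition H1 with
#' freshly randomized finger mappings in both sessions; each H2-starting
#' participant reuses the mapping sequence of one H1-starting participant,
#' so every mapping occurs exactly twice, once per condition.
#'
#' @param n_participants Even participant count (default 20).
#' @return Data frame with one row per session: \code{participant},
#'   \code{session} (1 or 2), \code{condition}, \code{mapping_id} and the
#'   mapping triple columns \code{m1, m2, m3}.
#' @export
counterbalanced_roster <- function(n_participants = 20) {
  stopifnot(n_participants %% 2 == 0)
  half <- n_participants / 2
  used <- NULL
  maps <- matrix(0L, 2 * half, 3)
  for (i in seq_len(2 * half)) {
    maps[i, ] <- draw_finger_mapping(used)
    used <- rbind(used, maps[i, ])
  }
  rows <- list()
  for (p in seq_len(half)) {
    m1 <- maps[2 * p - 1, ]; m2 <- maps[2 * p, ]
    rows[[length(rows) + 1]] <- data.frame(
      participant = p, session = 1:2, condition = c("H1", "H2"),
      mapping_id = c(2 * p - 1, 2 * p),
      m1 = c(m1[1], m2[1]), m2 = c(m1[2], m2[2]), m3 = c(m1[3], m2[3]))
    # paired H2-starter reuses the same mappings in the same order
    rows[[length(rows) + 1]] <- data.frame(
      participant = half + p, session = 1:2, condition = c("H2", "H1"),
      mapping_id = c(2 * p - 1, 2 * p),
      m1 = c(m1[1], m2[1]), m2 = c(m1[2], m2[2]), m3 = c(m1[3], m2[3]))
  }
  do.call(rbind, rows)
}
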