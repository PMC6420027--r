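#' Unfolded joint angles
#'
#' The analysis keeps joint angles on the real line: values outside
#' [0, 2*pi) are retained as-is, never wrapped, because the underlying
#' finger movements are not circular even though the goal-space effect of
#' the angles is. This is the identity on the data by construction and
#' exists to make the convention explicit (and auditable) at the entry of
#' the pipeline.
#'
#' @param angles Numeric vector or matrix of joint angles.
#' @return The input, unchanged, after a finiteness check.
#' @export
unfold_angles <- function(angles) {
  if (!all(is.finite(angles) | is.na(angles)))
    stop("angles must be finite or NA")
  angles
}

# stack the test postures of selected blocks of a session; missing trials
# dropped row-wise
session_test_postures <- function(session, blocks = NULL) {
  if (is.null(blocks)) blocks <- seq_along(session$blocks)
  rows <- lapply(session$blocks[blocks], function(b) {
    te <- b$test[!b$test$missing, , drop = FALSE]
    as.matrix(te[, c("q1", "q2", "q3")])
  })
  unfold_angles(do.call(rbind, rows))
}

final_test_postures <- function(session) {
  session_test_postures(session, length(session$blocks))
}

#' Pool test blocks into analysis windows
#'
#' Splits a session's test blocks into consecutive bins of
#' \code{bin_size} blocks and stacks the test-reach postures of each bin
#' into one matrix (missing trials dropped). Human sessions use
#' \code{bin_size = 3} (24 blocks -> 8 windows of 27 = 3 x 9 rows when
#' complete); agent sessions use \code{bin_size = 1} (10 windows of 9
#' rows).
#'
#' @param session A session record.
#' @param bin_size Blocks per window; must divide the block count.
#' @return List of posture matrices, one per window; windows with fewer
#'   than 4 rows carry attribute \code{degenerate = TRUE}.
#' @export
pool_windows <- function(session, bin_size = 3) {
  nb <- length(session$blocks)
  if (nb %% bin_size != 0)
    stop("bin_size must divide the number of blocks (", nb, ")")
  lapply(seq_len(nb / bin_size), function(w) {
    m <- session_test_postures(session, ((w - 1) * bin_size + 1):(w * bin_size))
    if (nrow(m) < 4) attr(m, "degenerate") <- TRUE
    m
  })
}

#' Motor-space synergies of one analysis window
#'
#' Covariance-based PCA of the window's postures after mean-centering,
#' with no scaling and no other pre-processing. Loadings follow a fixed
#' sign convention (the largest-magnitude component of each loading is
#' positive) so that loading comparisons across windows and individuals
#' are deterministic.
#'
#' @param mat Posture matrix (rows = reaches, columns = q1, q2, q3).
#' @return Object of class \code{"synergy_window"}: \code{loadings}
#'   (3 x 3, columns PC1..PC3), \code{variances}, \code{variance_fractions},
#'   \code{central_posture}, \code{n}.
#' @export
pca_synergies <- function(mat) {
  mat <- rbind(mat)
  if (nrow(mat) < 4) stop("insufficient data: need at least 4 postures")
  if (any(!is.finite(mat))) stop("postures must be finite")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("degenerate window: zero total variance")
  L <- pc$rotation
  for (j in 1:3) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  structure(list(loadings = L, variances = v,
                 variance_fractions = v / sum(v),
                 central_posture = colMeans(mat), n = nrow(mat)),
            class = "synergy_window")
}

#' @export
print.synergy_window <- function(x, ...) {
  cat("Synergy window (", x$n, " postures)\n", sep = "")
  cat("  variance fractions:",
      paste(round(x$variance_fractions, 3), collapse = " "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Solution location on the H1-H2 line
#'
#' Scalar projection coordinate of a central posture onto the line
#' connecting the two home postures in motor space:
#' s = <c - H1, H2 - H1> / |H2 - H1|^2, so s = 0 at H1, 1 at H2, and 0.5
#' at the baseline posture q* (the exact midpoint).
#'
#' @param central Central (mean) posture of a window.
#' @param H1,H2 Home postures.
#' @return Scalar s.
#' @export
project_central_posture <- function(central, H1, H2) {
  d <- H2 - H1
  n2 <- sum(d^2)
  if (n2 == 0) stop("home postures coincide")
  sum((central - H1) * d) / n2
}

#' Absolute q2 component of a synergy loading
#'
#' The relative use of the second degree of freedom in a principal
#' component: |q2 entry| of the unit-norm loading, in [0, 1]. Invariant
#' under the PCA sign ambiguity.
#'
#' @param result A \code{\link{pca_synergies}} result.
#' @param pc_index Which component (default 1).
#' @return Scalar in [0, 1].
#' @export
q2_loading <- function(result, pc_index = 1) {
  unname(abs(result$loadings[2, pc_index]))
}

#' Summed posture variance of a window
#'
#' Trace of the sample covariance of the postures: the total motor-space
#' variability, equal to the sum of the three synergy variances.
#'
#' @param mat Posture matrix.
#' @return Scalar total variance.
#' @export
summed_variance <- function(mat) {
  mat <- rbind(mat)
  if (nrow(mat) < 2) stop("need at least 2 postures")
  sum(apply(mat, 2, stats::var))
}

#' Per-block reach performance of a session
#'
#' Mean Euclidean goal-space distance between each block's test
#' reach-endpoints and their targets, with missing trials excluded; a
#' block with every trial missing yields NA and is flagged.
#'
#' @param session A session record.
#' @param geometry Geometry used for the baseline companion value.
#' @return Data frame: \code{block}, \code{mean_error}, \code{n_trials},
#'   \code{baseline}.
#' @export
performance_curve <- function(session, geometry = build_task_geometry()) {
  home <- if (session$condition == "H1") geometry$home_H1 else geometry$home_H2
  base <- baseline_error(home, geometry$test_targets, geometry$arm)
  rows <- lapply(session$blocks, function(b) {
    ok <- !b$test$missing
    data.frame(block = b$block,
               mean_error = if (any(ok)) mean(b$test$distance[ok]) else NA_real_,
               n_trials = sum(ok))
  })
  out <- do.call(rbind, rows)
  out$baseline <- base
  out
}

#' Full synergy analysis of a set of sessions
#'
#' Runs the windowed pipeline over every session: pooled windows, PCA
#' synergies, variance fractions, central-posture projection on the
#' H1-H2 line, |q2| loading of PC1, summed variance and per-block
#' performance. Degenerate windows (fewer than 4 rows or zero variance)
#' are dropped and counted.
#'
#' @param sessions List of session records (a \code{gb_population}'s or
#'   \code{human_population}'s \code{$sessions}, or any mix).
#' @param bin_size Blocks per analysis window (1 for agents, 3 for
#'   humans).
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @return List of class \code{"synergy_analysis"} of tidy data frames:
#'   \code{fractions} (id, condition, window, pc, variance_fraction),
#'   \code{location} (id, condition, window, s), \code{q2} (id,
#'   condition, window, q2_pc1), \code{variance} (id, condition, window,
#'   summed_variance), \code{performance} (id, condition, block,
#'   mean_error, baseline), and \code{n_degenerate}.
#' @export
analyze_sessions <- function(sessions, bin_size = 1,
                             geometry = build_task_geometry()) {
  H1 <- geometry$home_H1; H2 <- geometry$home_H2
  fr <- loc <- q2 <- sv <- perf <- list()
  n_deg <- 0L
  for (s in sessions) {
    wins <- pool_windows(s, bin_size)
    for (w in seq_along(wins)) {
      m <- wins[[w]]
      if (isTRUE(attr(m, "degenerate")) || nrow(m) < 4 ||
          sum(apply(m, 2, stats::var)) <= 0) {
        n_deg <- n_deg + 1L
        next
      }
      pc <- pca_synergies(m)
      fr[[length(fr) + 1]] <- data.frame(
        id = s$id, condition = s$condition, window = w, pc = 1:3,
        variance_fraction = pc$variance_fractions)
      loc[[length(loc) + 1]] <- data.frame(
        id = s$id, condition = s$condition, window = w,
        s = project_central_posture(pc$central_posture, H1, H2))
      q2[[length(q2) + 1]] <- data.frame(
        id = s$id, condition = s$condition, window = w,
        q2_pc1 = q2_loading(pc, 1))
      sv[[length(sv) + 1]] <- data.frame(
        id = s$id, condition = s$condition, window = w,
        summed_variance = summed_variance(m))
    }
    pf <- performance_curve(s, geometry)
    pf$id <- s$id; pf$condition <- s$condition
    if (!is.null(s$mapping_id)) pf$mapping_id <- s$mapping_id
    perf[[length(perf) + 1]] <- pf
  }
  structure(list(fractions = do.call(rbind, fr),
                 location = do.call(rbind, loc),
                 q2 = do.call(rbind, q2),
                 variance = do.call(rbind, sv),
                 performance = do.call(rbind, perf),
                 n_degenerate = n_deg, bin_size = bin_size),
            class = "synergy_analysis")
}

#' @export
print.synergy_analysis <- function(x, ...) {
  cat("Synergy analysis:", length(unique(x$fractions$id)), "sessions,",
      "bin size", x$bin_size, "\n")
  agg <- stats::aggregate(variance_fraction ~ condition + pc,
                          data = x$fractions[x$fractions$window ==
                                               max(x$fractions$window), ],
                          FUN = stats::median)
  cat("  final-window median variance fractions:\n")
  print(agg, row.names = FALSE)
  if (x$n_degenerate > 0)
    cat("  degenerate windows dropped:", x$n_degenerate, "\n")
  invisible(x)
}

#' Morphology-space versus task-space organization
#'
#' Two PCAs per analysis window on reach postures pooled across
#' participants: one in the task motor space (q1, q2, q3) and one in the
#' biological morphology space of finger elevations (left index, right
#' index, right middle), obtained by inverting each participant's finger
#' mapping. Because mappings are randomized, task-space consolidation
#' does not imply finger-space consolidation.
#'
#' @param population A \code{"human_population"} object (or any list of
#'   session records with mappings).
#' @param bin_size Blocks per window (default 3).
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @return Data frame: \code{window}, \code{space} ("task" or "fingers"),
#'   \code{pc}, \code{variance_fraction}, \code{n_rows}.
#' @export
morphology_vs_task_pca <- function(population, bin_size = 3,
                                   geometry = build_task_geometry()) {
  sessions <- if (inherits(population, "human_population"))
    population$sessions else population
  nb <- length(sessions[[1]]$blocks)
  n_win <- nb / bin_size
  out <- list()
  for (w in seq_len(n_win)) {
    qs <- list(); fs <- list()
    for (s in sessions) {
      m <- session_test_postures(s, ((w - 1) * bin_size + 1):(w * bin_size))
      if (nrow(m) == 0) next
      qs[[length(qs) + 1]] <- m
      fs[[length(fs) + 1]] <- t(apply(m, 1, posture_to_fingers,
                                      mapping = s$mapping,
                                      baseline = geometry$baseline_q_star))
    }
    for (sp in c("task", "fingers")) {
      M <- do.call(rbind, if (sp == "task") qs else fs)
      pc <- pca_synergies(M)
      out[[length(out) + 1]] <- data.frame(
        window = w, space = sp, pc = 1:3,
        variance_fraction = pc$variance_fractions, n_rows = nrow(M))
    }
  }
  do.call(rbind, out)
}

#' Principal angle between two planes in motor space
#'
#' Largest principal angle between the column spaces of two 3 x 2 bases,
#' in degrees; 0 for identical planes. Used to compare a recovered
#' synergy plane with a planted one.
#'
#' @param basis_a,basis_b 3 x 2 matrices with linearly independent
#'   columns.
#' @return Angle in degrees.
#' @export
principal_angle <- function(basis_a, basis_b) {
  qa <- qr.Q(qr(basis_a)); qb <- qr.Q(qr(basis_b))
  s <- svd(t(qa) %*% qb)$d
  s <- pmin(1, pmax(-1, s))
  max(acos(s)) * 180 / pi
}
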