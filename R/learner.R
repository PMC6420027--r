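#' Goal Babbling learner configuration
#'
#' Parameters of the online inverse-model learner. The defaults are the
#' study conditions: learning rate eta = 0.2, exploratory-noise amplitude
#' sigma = 0.5 with random-walk step sigma_delta = 0.005, home-target
#' probability 0.1, 40 training targets per block reached in 25
#' interpolation steps each (1000 online updates per block), 10 blocks.
#'
#' @param eta Learning rate of the online gradient update.
#' @param sigma Exploratory-noise amplitude (rad): the induced posture
#'   perturbation has standard deviation sigma per joint over the unit
#'   goal box.
#' @param sigma_delta Per-step standard deviation of the Gaussian random
#'   walk on the noise coefficients.
#' @param bandwidth Responsibility width of the local models in goal
#'   units; \code{NULL} uses the median nearest-neighbour spacing of the
#'   prototype centres.
#' @param prototypes Optional matrix of prototype centres in goal space;
#'   \code{NULL} uses the 16 training targets.
#' @param direction_weighting Weight each update by
#'   max(0, cos(achieved movement, intended movement)).
#' @param efficiency_weighting Weight each update by
#'   min(1, goal-space displacement / motor-space displacement).
#' @param effort_weight In [0, 1]: fraction of the null-space deviation
#'   from the home posture removed from each executed posture (1 = every
#'   executed posture is first-order effort-optimal for its endpoint).
#' @param home_target_prob Probability that a drawn training target is
#'   replaced by the home endpoint.
#' @param steps_per_target Interpolation steps per target transition.
#' @param targets_per_block Targets drawn per training block.
#' @param n_blocks Number of training blocks (each followed by a test).
#' @return A list of class \code{"gb_config"}.
#' @export
gb_config <- function(eta = 0.2, sigma = 0.5, sigma_delta = 0.005,
                      bandwidth = NULL, prototypes = NULL,
                      direction_weighting = TRUE,
                      efficiency_weighting = TRUE,
                      effort_weight = 1,
                      home_target_prob = 0.1, steps_per_target = 25,
                      targets_per_block = 40, n_blocks = 10) {
  stopifnot(eta >= 0, sigma >= 0, sigma_delta >= 0,
            home_target_prob >= 0, home_target_prob <= 1,
            effort_weight >= 0, effort_weight <= 1,
            steps_per_target >= 1, targets_per_block >= 1, n_blocks >= 1)
  structure(as.list(environment()), class = "gb_config")
}

# amplitude metric over the unit goal box [-1,1]^2 for u = (x, y, 1):
# E[x^2] = E[y^2] = 1/3, cross moments vanish
.noise_row_norm <- function(A) {
  sqrt((A[, 1L]^2 + A[, 2L]^2) / 3 + A[, 3L]^2)
}

.normalize_noise <- function(A, sigma) {
  if (sigma == 0) return(matrix(0, 3, 3))
  A * (sigma / .noise_row_norm(A))
}

#' Initialize a Goal Babbling learner
#'
#' The initial inverse model maps every goal onto the home posture (zero
#' gains, home offsets), so the untrained agent rests at home whatever the
#' target. Noise-walk coefficients are drawn from the current RNG state
#' and rescaled so the induced perturbation has standard deviation about
#' sigma per joint over the goal region; all three joints receive equal
#' noise amplitude by construction.
#'
#' @param home Home posture (3 joint angles) seeding learning.
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @param config A \code{\link{gb_config}} object.
#' @return An environment of class \code{"gb_learner"} holding the local
#'   affine models, the noise-walk state and the update counter. It has
#'   reference semantics: training functions modify it in place.
#' @export
init_learner <- function(home, geometry = build_task_geometry(),
                         config = gb_config()) {
  home <- check_posture(home)
  C <- if (is.null(config$prototypes)) geometry$training_targets else
    rbind(config$prototypes)
  K <- nrow(C)
  h <- config$bandwidth
  if (is.null(h)) {
    if (K > 1) {
      D <- as.matrix(stats::dist(C)); diag(D) <- Inf
      h <- stats::median(apply(D, 1, min))
    } else h <- 0.2
  }
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$arm <- geometry$arm
  st$l <- unname(as.numeric(geometry$arm))
  st$home <- home
  st$home_goal <- forward_kinematics(home, geometry$arm)
  st$C <- C
  st$h <- h
  st$Gx <- matrix(0, K, 3)
  st$Gy <- matrix(0, K, 3)
  st$B <- matrix(rep(home, each = K), K, 3)
  st$A <- .normalize_noise(matrix(stats::rnorm(9), 3, 3), config$sigma)
  st$x_prev <- st$home_goal
  st$q_prev <- home
  st$n_updates <- 0L
  class(st) <- "gb_learner"
  st
}

.responsibilities <- function(st, g) {
  d2 <- (st$C[, 1L] - g[1L])^2 + (st$C[, 2L] - g[2L])^2
  w <- exp(-d2 / (2 * st$h * st$h))
  w / sum(w)
}

#' Predict a posture from the current inverse model
#'
#' Responsibility-weighted mixture of the local affine maps: Gaussian
#' weights in goal distance to the prototype centres, normalized to sum
#' to one.
#'
#' @param state A \code{"gb_learner"} object.
#' @param goal Goal point \code{c(x, y)} or a two-column matrix.
#' @return A posture (3-vector), or a matrix of postures for matrix input.
#' @export
predict_posture <- function(state, goal) {
  if (is.matrix(goal))
    return(t(apply(goal, 1, function(g) predict_posture(state, g))))
  w <- .responsibilities(state, goal)
  drop(colSums(w * (state$B + goal[1L] * state$Gx + goal[2L] * state$Gy)))
}

#' @export
predict.gb_learner <- function(object, newdata, ...) {
  predict_posture(object, newdata)
}

#' Advance the exploratory-noise random walk and evaluate it
#'
#' The perturbation is affine in the goal, e = A (x, y, 1)', with every
#' coefficient of A performing a Gaussian random walk (per-step sd
#' sigma_delta) and A renormalized after each step so the induced
#' perturbation amplitude stays at sigma over the goal region, equally for
#' all three joints. Mutates the walk state in place and uses the current
#' RNG stream.
#'
#' @param state A \code{"gb_learner"} object.
#' @param goal Goal point at which the perturbation is evaluated.
#' @return Numeric 3-vector of joint perturbations (rad).
#' @export
exploratory_perturbation <- function(state, goal) {
  cfg <- state$config
  if (cfg$sigma == 0) return(c(0, 0, 0))
  if (cfg$sigma_delta > 0)
    state$A <- .normalize_noise(
      state$A + cfg$sigma_delta * matrix(stats::rnorm(9), 3, 3), cfg$sigma)
  drop(state$A %*% c(goal[1L], goal[2L], 1))
}

#' One online training step
#'
#' Executes the current inverse-model estimate for a sub-target with
#' exploratory noise added, relaxes the executed posture towards home
#' within the Jacobian null space (effort minimization; endpoint unchanged
#' to first order), observes the actual endpoint, and performs one
#' responsibility-weighted gradient step pulling the model's prediction at
#' the \emph{observed} endpoint towards the executed posture. Regressing
#' on the observed outcome rather than the intended one is what lets the
#' inverse model be learned directly. Increments the update counter by 1.
#'
#' @param state A \code{"gb_learner"} object (modified in place).
#' @param sub_target Goal point for this step.
#' @return Invisibly, a list log: \code{sub_target}, \code{posture},
#'   \code{endpoint}, \code{step_error}, \code{weight}.
#' @export
training_step <- function(state, sub_target) {
  cfg <- state$config
  l <- state$l
  g <- sub_target
  w_g <- .responsibilities(state, g)
  qhat <- colSums(w_g * (state$B + g[1L] * state$Gx + g[2L] * state$Gy))
  e <- exploratory_perturbation(state, g)
  qp <- qhat + e
  if (cfg$effort_weight > 0 && cfg$sigma > 0) {
    # relax towards home within the null space of the task Jacobian:
    # qp + a * (I - J+ J) (home - qp), with the 2x2 system solved in place
    a1 <- qp[1L]; a2 <- a1 + qp[2L]; a3 <- a2 + qp[3L]
    s1 <- l[1L] * sin(a1); s2 <- l[2L] * sin(a2); s3 <- l[3L] * sin(a3)
    c1 <- l[1L] * cos(a1); c2 <- l[2L] * cos(a2); c3 <- l[3L] * cos(a3)
    jx <- c(-(s1 + s2 + s3), -(s2 + s3), -s3)
    jy <- c(c1 + c2 + c3, c2 + c3, c3)
    dq <- state$home - qp
    v1 <- sum(jx * dq); v2 <- sum(jy * dq)
    m11 <- sum(jx * jx) + 1e-10; m22 <- sum(jy * jy) + 1e-10
    m12 <- sum(jx * jy)
    det <- m11 * m22 - m12 * m12
    u1 <- (m22 * v1 - m12 * v2) / det
    u2 <- (m11 * v2 - m12 * v1) / det
    qp <- qp + cfg$effort_weight * (dq - jx * u1 - jy * u2)
  }
  a1 <- qp[1L]; a2 <- a1 + qp[2L]; a3 <- a2 + qp[3L]
  xo <- c(l[1L] * cos(a1) + l[2L] * cos(a2) + l[3L] * cos(a3),
          l[1L] * sin(a1) + l[2L] * sin(a2) + l[3L] * sin(a3))
  wd <- 1
  if (cfg$direction_weighting) {
    v1 <- xo - state$x_prev
    v2 <- g - state$x_prev
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 > 0 && n2 > 0) wd <- max(0, sum(v1 * v2) / (n1 * n2))
  }
  if (cfg$efficiency_weighting) {
    dq <- sqrt(sum((qp - state$q_prev)^2))
    if (dq > 1e-12)
      wd <- wd * min(1, sqrt(sum((xo - state$x_prev)^2)) / dq)
  }
  w_o <- .responsibilities(state, xo)
  err <- colSums(w_o * (state$B + xo[1L] * state$Gx + xo[2L] * state$Gy)) - qp
  sc <- cfg$eta * wd * w_o
  state$B <- state$B - outer(sc, err)
  state$Gx <- state$Gx - outer(sc * xo[1L], err)
  state$Gy <- state$Gy - outer(sc * xo[2L], err)
  state$x_prev <- xo
  state$q_prev <- qp
  state$n_updates <- state$n_updates + 1L
  invisible(list(sub_target = g, posture = qp, endpoint = xo,
                 step_error = sqrt(sum((xo - g)^2)), weight = wd))
}

# draw the per-block target sequence: iid from the training targets, each
# draw replaced by the home endpoint with the configured probability
draw_block_targets <- function(geometry, home_goal, n_targets, p_home) {
  idx <- sample.int(nrow(geometry$training_targets), n_targets, replace = TRUE)
  tg <- geometry$training_targets[idx, , drop = FALSE]
  is_home <- stats::runif(n_targets) < p_home
  tg[is_home, 1L] <- home_goal[1L]
  tg[is_home, 2L] <- home_goal[2L]
  attr(tg, "is_home") <- is_home
  tg
}

#' Run one training block
#'
#' Draws the block's training targets (home endpoint substituted with the
#' configured probability), linearly interpolates between consecutive
#' targets in goal space, and performs one \code{\link{training_step}} per
#' interpolation step: with the defaults, 40 targets times 25 steps =
#' 1000 online updates. The first transition starts from the home
#' endpoint.
#'
#' @param state A \code{"gb_learner"} object (modified in place).
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @param record_subtargets Also return the full sub-target sequence.
#' @return Invisibly, a list with \code{targets}, \code{mean_step_error},
#'   \code{n_updates} performed in this block and, on request,
#'   \code{subtargets}.
#' @export
run_training_block <- function(state, geometry = build_task_geometry(),
                               record_subtargets = FALSE) {
  cfg <- state$config
  tg <- draw_block_targets(geometry, state$home_goal,
                           cfg$targets_per_block, cfg$home_target_prob)
  cur <- state$home_goal
  nstep <- cfg$steps_per_target
  tot <- 0
  subs <- if (record_subtargets)
    matrix(NA_real_, nrow(tg) * nstep, 2) else NULL
  k <- 0
  for (tn in seq_len(nrow(tg))) {
    nxt <- tg[tn, ]
    for (s in seq_len(nstep)) {
      sub <- cur + (nxt - cur) * s / nstep
      lg <- training_step(state, sub)
      tot <- tot + lg$step_error
      k <- k + 1
      if (record_subtargets) subs[k, ] <- sub
    }
    cur <- nxt
  }
  invisible(list(targets = tg,
                 mean_step_error = tot / (nrow(tg) * nstep),
                 n_updates = as.integer(nrow(tg) * nstep),
                 subtargets = subs))
}

#' Evaluate the current inverse model on the test targets
#'
#' Pure read-out: for each of the nine test targets the posture is
#' predicted with no exploratory noise and no learning, and its endpoint
#' and distance to the target are recorded. The learner state is left
#' untouched.
#'
#' @param state A \code{"gb_learner"} object.
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @return Data frame with one row per test target: \code{target_x},
#'   \code{target_y}, \code{q1..q3}, \code{x}, \code{y}, \code{distance}.
#' @export
evaluate_test <- function(state, geometry = build_task_geometry()) {
  tt <- geometry$test_targets
  P <- predict_posture(state, tt)
  E <- forward_kinematics(P, state$arm)
  data.frame(target_x = tt[, 1L], target_y = tt[, 2L],
             q1 = P[, 1L], q2 = P[, 2L], q3 = P[, 3L],
             x = E[, 1L], y = E[, 2L],
             distance = sqrt(rowSums((E - tt)^2)),
             missing = FALSE)
}

# snapshot of all numeric state, for no-learning contracts
learner_state_snapshot <- function(state) {
  list(Gx = state$Gx, Gy = state$Gy, B = state$B, A = state$A,
       x_prev = state$x_prev, q_prev = state$q_prev,
       n_updates = state$n_updates)
}

#' @export
print.gb_learner <- function(x, ...) {
  cat("Goal Babbling learner:", nrow(x$C), "local affine models,",
      x$n_updates, "updates\n")
  cat("  home posture:", paste(round(x$home, 3), collapse = ", "), "\n")
  invisible(x)
}
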