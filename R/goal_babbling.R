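#' Train a Goal Babbling agent
#'
#' The package's central fitting function: trains one simulated agent on
#' the redundant planar reaching task by Goal Babbling — direct online
#' learning of the inverse model with goal-guided exploratory noise —
#' starting from one of the two home postures. Training runs
#' \code{config$n_blocks} blocks of 1000 online updates each, with the
#' learning dynamics disabled for a nine-target test read-out after every
#' block.
#'
#' @param condition \code{"H1"} or \code{"H2"}: which home posture seeds
#'   learning.
#' @param geometry A \code{\link{build_task_geometry}} object.
#' @param config A \code{\link{gb_config}} object.
#' @param seed Integer seed; every source of randomness in the run
#'   derives from it.
#' @param id Session identifier stored in the session record.
#' @return An object of class \code{"gb_fit"}: list with the trained
#'   \code{learner}, the per-block \code{errors} (mean test distance), the
#'   \code{session} record (common session schema), \code{condition},
#'   \code{geometry}, \code{config} and \code{baseline} error.
#' @seealso \code{\link{run_population}} for the 100-agent populations,
#'   \code{\link{analyze_sessions}} for the synergy pipeline.
#' @examples
#' fit <- goal_babbling("H2", config = gb_config(n_blocks = 2), seed = 1)
#' print(fit)
#' @export
goal_babbling <- function(condition = c("H1", "H2"),
                          geometry = build_task_geometry(),
                          config = gb_config(), seed = 1L,
                          id = NULL) {
  condition <- match.arg(condition)
  home <- if (condition == "H1") geometry$home_H1 else geometry$home_H2
  set.seed(seed)
  st <- init_learner(home, geometry, config)
  errors <- numeric(config$n_blocks)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    tr <- run_training_block(st, geometry)
    te <- evaluate_test(st, geometry)
    errors[b] <- mean(te$distance)
    blocks[[b]] <- list(block = b,
                        training = list(mean_step_error = tr$mean_step_error,
                                        n_updates = tr$n_updates),
                        test = te)
  }
  if (is.null(id)) id <- sprintf("agent-%s-seed%d", condition, seed)
  session <- list(schema = session_schema_version(), id = id, kind = "agent",
                  condition = condition, mapping = NULL, seed = seed,
                  n_blocks = config$n_blocks, blocks = blocks)
  structure(list(learner = st, errors = errors, session = session,
                 condition = condition, geometry = geometry, config = config,
                 seed = seed,
                 baseline = baseline_error(home, geometry$test_targets,
                                           geometry$arm)),
            class = "gb_fit")
}

#' @export
print.gb_fit <- function(x, ...) {
  cat("Goal Babbling agent (condition ", x$condition, ", ",
      x$config$n_blocks, " blocks, seed ", x$seed, ")\n", sep = "")
  cat("  mean test error: block 1 = ", round(x$errors[1], 3),
      ", final = ", round(x$errors[length(x$errors)], 3),
      " (baseline ", round(x$baseline, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.gb_fit <- function(object, ...) {
  fin <- final_test_postures(object$session)
  pc <- pca_synergies(fin)
  out <- list(condition = object$condition,
              errors = object$errors, baseline = object$baseline,
              final_variance_fractions = pc$variance_fractions,
              final_central_posture = pc$central_posture,
              n_updates = object$learner$n_updates)
  class(out) <- "summary.gb_fit"
  out
}

#' @export
print.summary.gb_fit <- function(x, ...) {
  cat("Goal Babbling agent, condition", x$condition, "\n")
  cat("  updates:", x$n_updates, "\n")
  cat("  mean test error per block:\n   ",
      paste(round(x$errors, 3), collapse = " "), "\n")
  cat("  baseline (no movement):", round(x$baseline, 3), "\n")
  cat("  final-block synergies, variance fractions:",
      paste(round(x$final_variance_fractions, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
predict.gb_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$geometry$test_targets
  predict_posture(object$learner, newdata)
}

#' @export
coef.gb_fit <- function(object, ...) {
  list(centres = object$learner$C, gain_x = object$learner$Gx,
       gain_y = object$learner$Gy, offset = object$learner$B)
}

#' @export
residuals.gb_fit <- function(object, ...) {
  te <- object$session$blocks[[length(object$session$blocks)]]$test
  cbind(x = te$x - te$target_x, y = te$y - te$target_y)
}

#' @export
plot.gb_fit <- function(x, ...) {
  plot(seq_along(x$errors), x$errors, type = "b", pch = 16,
       xlab = "training block", ylab = "mean test error",
       ylim = c(0, max(x$errors, x$baseline)), ...)
  graphics::abline(h = x$baseline, lty = 2)
  graphics::legend("bottomleft", c("agent", "baseline (no movement)"),
                   lty = c(1, 2), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' Simulate a population of Goal Babbling agents
#'
#' Trains \code{n_agents} independent agents in one condition; agent i
#' uses seed \code{base_seed + i}, so populations are reproducible and
#' the seed stream does not depend on the condition (paired noise across
#' conditions).
#'
#' @param condition \code{"H1"} or \code{"H2"}.
#' @param n_agents Number of agents (the study populations use 100).
#' @param base_seed Population base seed.
#' @inheritParams goal_babbling
#' @return Object of class \code{"gb_population"}: list with
#'   \code{condition}, \code{sessions} (one session record per agent) and
#'   \code{baseline}.
#' @export
run_population <- function(condition = c("H1", "H2"), n_agents = 100,
                           geometry = build_task_geometry(),
                           config = gb_config(), base_seed = 0L) {
  condition <- match.arg(condition)
  sessions <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    fit <- goal_babbling(condition, geometry, config,
                         seed = base_seed + i,
                         id = sprintf("agent-%s-%03d", condition, i))
    sessions[[i]] <- fit$session
  }
  home <- if (condition == "H1") geometry$home_H1 else geometry$home_H2
  structure(list(condition = condition, sessions = sessions,
                 geometry = geometry, config = config,
                 base_seed = base_seed,
                 baseline = baseline_error(home, geometry$test_targets,
                                           geometry$arm)),
            class = "gb_population")
}

#' @export
print.gb_population <- function(x, ...) {
  cat("Goal Babbling population: ", length(x$sessions), " agents, condition ",
      x$condition, "\n", sep = "")
  m <- population_error_curve(x)
  cat("  median mean test error, block 1 -> ", nrow(m), ": ",
      round(m$median_error[1], 3), " -> ",
      round(m$median_error[nrow(m)], 3),
      " (baseline ", round(x$baseline, 3), ")\n", sep = "")
  invisible(x)
}

#' Population learning curve
#'
#' Across-agent median and quartiles of the per-block mean test error.
#'
#' @param population A \code{"gb_population"} object.
#' @return Data frame: \code{block}, \code{median_error}, \code{q25},
#'   \code{q75}.
#' @export
population_error_curve <- function(population) {
  E <- sapply(population$sessions, function(s)
    sapply(s$blocks, function(b) mean(b$test$distance[!b$test$missing])))
  E <- rbind(E)  # blocks x agents
  data.frame(block = seq_len(nrow(E)),
             median_error = apply(E, 1, stats::median),
             q25 = apply(E, 1, stats::quantile, 0.25),
             q75 = apply(E, 1, stats::quantile, 0.75))
}

#' @export
plot.gb_population <- function(x, ...) {
  m <- population_error_curve(x)
  plot(m$block, m$median_error, type = "b", pch = 16,
       ylim = c(0, max(m$q75, x$baseline)),
       xlab = "training block", ylab = "mean test error (median, IQR)", ...)
  graphics::arrows(m$block, m$q25, m$block, m$q75, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = x$baseline, lty = 2)
  invisible(x)
}
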