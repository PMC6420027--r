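geo <- build_task_geometry()

test_that("the initial inverse model maps every goal onto the home posture", {
  set.seed(1)
  st <- init_learner(geo$home_H1, geo)
  P <- predict_posture(st, geo$training_targets)
  expect_equal(max(abs(sweep(P, 2, geo$home_H1))), 0)
  expect_equal(predict_posture(st, c(0.83, -0.4)), geo$home_H1)
  # degenerate noise amplitude: perturbation is exactly zero
  set.seed(1)
  st0 <- init_learner(geo$home_H2, geo, gb_config(sigma = 0))
  expect_identical(exploratory_perturbation(st0, c(0.3, 0.3)), c(0, 0, 0))
  expect_identical(exploratory_perturbation(st0, c(-0.9, 0.7)), c(0, 0, 0))
  # determinism contract: same seed, bitwise-identical coefficients
  set.seed(42); a <- init_learner(geo$home_H1, geo)
  set.seed(42); b <- init_learner(geo$home_H1, geo)
  expect_identical(a$A, b$A)
  expect_identical(a$B, b$B)
})

test_that("posture prediction is the responsibility-weighted affine mixture", {
  set.seed(2)
  # single prototype, zero gain: constant map
  st <- init_learner(geo$home_H1, geo,
                     gb_config(prototypes = matrix(c(0.2, 0.5), 1)))
  p <- c(1.1, -0.3, 2.2)
  st$B <- matrix(p, 1, 3, byrow = TRUE)
  expect_equal(predict_posture(st, c(0.9, -0.9)), p)
  expect_equal(predict_posture(st, c(0, 0)), p)
  # two prototypes: compare against a scalar re-implementation
  st2 <- init_learner(geo$home_H1, geo,
                      gb_config(prototypes = rbind(c(0, 0), c(1, 0)),
                                bandwidth = 0.4))
  st2$B <- rbind(c(1, 2, 3), c(-1, 0, 2))
  st2$Gx <- rbind(c(0.1, 0, -0.2), c(0, 0.3, 0))
  st2$Gy <- rbind(c(0, -0.1, 0), c(0.2, 0, 0.1))
  g <- c(0.3, -0.2)
  w1 <- exp(-sum((g - c(0, 0))^2) / (2 * 0.4^2))
  w2 <- exp(-sum((g - c(1, 0))^2) / (2 * 0.4^2))
  pred <- (w1 * (st2$B[1, ] + g[1] * st2$Gx[1, ] + g[2] * st2$Gy[1, ]) +
             w2 * (st2$B[2, ] + g[1] * st2$Gx[2, ] + g[2] * st2$Gy[2, ])) /
    (w1 + w2)
  expect_equal(predict_posture(st2, g), pred, tolerance = 1e-12)
})

test_that("exploratory noise has amplitude sigma, equal across joints, and walk-step continuity", {
  # frozen walk: sigma_delta = 0 keeps the perturbation constant
  set.seed(3)
  st <- init_learner(geo$home_H1, geo, gb_config(sigma_delta = 0))
  g <- c(0.4, 0.4)
  expect_identical(exploratory_perturbation(st, g),
                   exploratory_perturbation(st, g))
  # amplitude: sample sd of each joint's perturbation near sigma at a
  # mid-range goal; a faster walk step gives the Monte-Carlo estimate
  # power without changing the normalized amplitude
  set.seed(4)
  st <- init_learner(geo$home_H1, geo, gb_config(sigma = 0.5,
                                                 sigma_delta = 0.05))
  gfix <- c(0.6, 0.6)
  E <- matrix(0, 1e5, 3)
  for (t in seq_len(1e5)) E[t, ] <- exploratory_perturbation(st, gfix)
  sds <- apply(E, 2, sd)
  expect_true(all(sds > 0.8 * 0.5 & sds < 1.2 * 0.5))
  # continuity: mean per-step change scales linearly in sigma_delta
  step_mean <- function(sd_delta, seed) {
    set.seed(seed)
    st <- init_learner(geo$home_H1, geo,
                       gb_config(sigma = 0.5, sigma_delta = sd_delta))
    E <- matrix(0, 2e4, 3)
    for (t in seq_len(2e4)) E[t, ] <- exploratory_perturbation(st, gfix)
    mean(sqrt(rowSums((E[-1, ] - E[-2e4, ])^2)))
  }
  ratio <- step_mean(0.02, 9) / step_mean(0.01, 9)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("a training step is a no-op at eta = 0, sigma = 0 and counts updates", {
  set.seed(5)
  st <- init_learner(geo$home_H2, geo, gb_config(eta = 0, sigma = 0))
  before <- goalbabbling:::learner_state_snapshot(st)
  training_step(st, c(0.2, 0.4))
  after <- goalbabbling:::learner_state_snapshot(st)
  expect_identical(before$B, after$B)
  expect_identical(before$Gx, after$Gx)
  expect_identical(before$Gy, after$Gy)
  expect_identical(after$n_updates, 1L)
  training_step(st, c(0.1, 0.1))
  expect_identical(st$n_updates, 2L)
})

test_that("the online update equals the explicit least-mean-squares delta", {
  # single global prototype, uniform weight, no weighting terms: the
  # update must equal the hand-computed gradient step
  set.seed(6)
  cfg <- gb_config(eta = 0.3, sigma = 0, effort_weight = 0,
                   direction_weighting = FALSE,
                   efficiency_weighting = FALSE,
                   prototypes = matrix(c(0.2, 0.3), 1))
  st <- init_learner(geo$home_H1, geo, cfg)
  st$B <- matrix(c(1, 2, 3), 1)
  st$Gx <- matrix(c(0.2, -0.1, 0), 1)
  st$Gy <- matrix(c(0, 0.1, -0.3), 1)
  B0 <- st$B; Gx0 <- st$Gx; Gy0 <- st$Gy
  g <- c(0.5, 0.2)
  qp <- drop(B0 + g[1] * Gx0 + g[2] * Gy0)  # sigma = 0: executed = predicted
  xo <- forward_kinematics(qp)
  err <- drop(B0 + xo[1] * Gx0 + xo[2] * Gy0) - qp
  training_step(st, g)
  expect_equal(drop(st$B), drop(B0) - 0.3 * err, tolerance = 1e-12)
  expect_equal(drop(st$Gx), drop(Gx0) - 0.3 * xo[1] * err, tolerance = 1e-12)
  expect_equal(drop(st$Gy), drop(Gy0) - 0.3 * xo[2] * err, tolerance = 1e-12)
})

test_that("one training block performs exactly 1000 updates along linear interpolations", {
  set.seed(7)
  st <- init_learner(geo$home_H1, geo)
  lg <- run_training_block(st, geo, record_subtargets = TRUE)
  expect_identical(st$n_updates, 1000L)
  expect_identical(lg$n_updates, 1000L)
  # each 25-step transition is an arithmetic progression in both
  # coordinates, ending exactly at the drawn target
  for (tn in c(1, 17, 40)) {
    seg <- lg$subtargets[((tn - 1) * 25 + 1):(tn * 25), ]
    expect_lt(max(abs(diff(diff(seg[, 1])))), 1e-12)
    expect_lt(max(abs(diff(diff(seg[, 2])))), 1e-12)
    expect_equal(unname(seg[25, ]), unname(lg$targets[tn, ]))
  }
  run_training_block(st, geo)
  expect_identical(st$n_updates, 2000L)
})

test_that("home-endpoint substitution happens at the configured rate", {
  set.seed(8)
  home_goal <- forward_kinematics(geo$home_H1)
  n_home <- 0L; n_tot <- 0L
  for (b in 1:10000) {
    tg <- goalbabbling:::draw_block_targets(geo, home_goal, 40, 0.1)
    n_home <- n_home + sum(attr(tg, "is_home"))
    n_tot <- n_tot + 40L
  }
  expect_gt(n_home / n_tot, 0.09)
  expect_lt(n_home / n_tot, 0.11)
})

test_that("test evaluation reads the model out without touching it", {
  set.seed(9)
  st <- init_learner(geo$home_H2, geo)
  te <- evaluate_test(st, geo)
  expect_equal(nrow(te), 9)
  ep <- forward_kinematics(geo$home_H2)
  expect_true(all(abs(te$x - ep[1]) < 1e-12))
  expect_true(all(abs(te$y - ep[2]) < 1e-12))
  expect_equal(mean(te$distance),
               baseline_error(geo$home_H2, geo$test_targets))
  run_training_block(st, geo)
  before <- goalbabbling:::learner_state_snapshot(st)
  invisible(evaluate_test(st, geo))
  expect_identical(before, goalbabbling:::learner_state_snapshot(st))
})

test_that("damped-least-squares IK bounds the achievable test error", {
  # an oracle inverse model: IK per target in place of the learned map
  errs <- sapply(seq_len(9), function(i) {
    dls_ik(geo$test_targets[i, ], geo$home_H1)$error
  })
  expect_lt(mean(errs), 0.01)
})

test_that("populations are deterministic and carry the session schema", {
  cfg <- gb_config(n_blocks = 2)
  p1 <- run_population("H1", n_agents = 3, config = cfg, base_seed = 7)
  p2 <- run_population("H1", n_agents = 3, config = cfg, base_seed = 7)
  expect_identical(p1$sessions, p2$sessions)
  expect_length(p1$sessions, 3)
  s <- p1$sessions[[1]]
  expect_identical(s$kind, "agent")
  expect_identical(s$condition, "H1")
  expect_length(s$blocks, 2)
  expect_equal(nrow(s$blocks[[1]]$test), 9)
  expect_equal(s$blocks[[2]]$training$n_updates, 1000)
})
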