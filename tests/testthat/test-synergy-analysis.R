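geo <- build_task_geometry()

test_that("angle unfolding keeps out-of-range values, which are goal-equivalent", {
  expect_equal(unfold_angles(-0.5), -0.5)
  expect_equal(unfold_angles(c(0.3, 6.1)), c(0.3, 6.1))
  q <- c(-pi, 7, 3 * pi)
  expect_equal(forward_kinematics(unfold_angles(q)),
               forward_kinematics(q %% (2 * pi)), tolerance = 1e-12)
  expect_error(unfold_angles(c(1, Inf)))
})

test_that("windows pool three blocks into 27 rows and drop missing trials", {
  ses <- clean_human_session("H1", seed = 20)
  w <- pool_windows(ses, 3)
  expect_length(w, 8)
  expect_true(all(sapply(w, nrow) == 27))
  # flag two trials of block 1 missing: first window loses two rows
  ses$blocks[[1]]$test$missing[c(2, 5)] <- TRUE
  ses$blocks[[1]]$test[c(2, 5), c("q1", "q2", "q3", "x", "y",
                                  "distance")] <- NA_real_
  expect_equal(nrow(pool_windows(ses, 3)[[1]]), 25)
  # agents: one window per block
  fit <- goal_babbling("H1", config = gb_config(n_blocks = 10), seed = 30)
  expect_length(pool_windows(fit$session, 1), 10)
  expect_error(pool_windows(ses, 5), "divide")
})

test_that("window PCA matches an explicit covariance eigendecomposition", {
  set.seed(12)
  # rank-1 cloud: a line in motor space
  tvals <- seq(-1, 1, length.out = 27)
  dirv <- c(2, -1, 0.5) / sqrt(5.25)
  line <- outer(tvals, dirv) + rep(c(0.4, 1, 2), each = 27)
  pc <- pca_synergies(line)
  expect_equal(pc$variance_fractions, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(abs(sum(pc$loadings[, 1] * dirv)), 1, tolerance = 1e-10)
  # rank-2 cloud: planted ellipse, zero out-of-plane noise
  basis <- qr.Q(qr(cbind(c(1, 1, 0), c(0, 1, 1))))
  ang <- seq(0, 2 * pi, length.out = 27)
  ell <- cbind(0.8 * cos(ang), 0.3 * sin(ang)) %*% t(basis)
  pc2 <- pca_synergies(ell)
  expect_lt(pc2$variance_fractions[3], 1e-12)
  expect_lt(principal_angle(pc2$loadings[, 1:2], basis), 1e-6)
  # random cloud against the eigen oracle
  M <- matrix(rnorm(81), 27, 3)
  pc3 <- pca_synergies(M)
  ev <- eigen(cov(M), symmetric = TRUE)
  expect_equal(pc3$variance_fractions, ev$values / sum(ev$values),
               tolerance = 1e-10)
  for (j in 1:3)
    expect_equal(abs(sum(pc3$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-10)
  # sign convention: the largest-magnitude entry of each loading is
  # positive, making loadings deterministic
  expect_true(all(apply(pc3$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_error(pca_synergies(M[1:3, ]), "insufficient")
  expect_error(pca_synergies(matrix(1, 10, 3)), "degenerate")
})

test_that("variance fractions sum to one and are rotation-equivariant", {
  set.seed(13)
  for (rep in 1:10) {
    M <- matrix(rnorm(30 * 3, sd = runif(1, 0.1, 2)), 30, 3)
    pc <- pca_synergies(M)
    expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-10)
    R <- random_rotation()
    pcr <- pca_synergies(M %*% t(R))
    expect_equal(pcr$variance_fractions, pc$variance_fractions,
                 tolerance = 1e-8)
    for (j in 1:3)
      expect_equal(abs(sum(pcr$loadings[, j] * (R %*% pc$loadings[, j]))),
                   1, tolerance = 1e-8)
  }
})

test_that("the central-posture projection is an affine coordinate on the H1-H2 line", {
  H1 <- geo$home_H1; H2 <- geo$home_H2
  expect_equal(project_central_posture(H1, H1, H2), 0)
  expect_equal(project_central_posture(H2, H1, H2), 1)
  expect_equal(project_central_posture(geo$baseline_q_star, H1, H2), 0.5,
               tolerance = 1e-3)
  set.seed(14)
  c0 <- runif(3)
  s0 <- project_central_posture(c0, H1, H2)
  d <- H2 - H1
  v <- rnorm(3); v <- v - sum(v * d) / sum(d^2) * d  # orthogonal to the line
  expect_equal(project_central_posture(c0 + 3 * v, H1, H2), s0,
               tolerance = 1e-10)
  expect_error(project_central_posture(c0, H1, H1), "coincide")
})

test_that("q2 loading extraction is sign-invariant and matches planted bases", {
  fake <- list(loadings = diag(3)[, c(2, 1, 3)])
  expect_equal(q2_loading(fake, 1), 1)
  expect_equal(q2_loading(fake, 2), 0)
  set.seed(15)
  basis <- qr.Q(qr(matrix(rnorm(6), 3, 2)))
  ang <- seq(0, 2 * pi, length.out = 30)
  pts <- cbind(2 * cos(ang), 0.5 * sin(ang)) %*% t(basis)
  pc <- pca_synergies(pts)
  expect_equal(q2_loading(pc, 1), abs(basis[2, 1]), tolerance = 1e-8)
  flipped <- list(loadings = -pc$loadings)
  expect_equal(q2_loading(flipped, 1), q2_loading(pc, 1))
})

test_that("summed variance is the trace of the posture covariance", {
  expect_equal(summed_variance(matrix(2, 5, 3)), 0)
  toy <- rbind(c(0, 0, 0), c(1, 2, 0), c(2, 0, 3))
  expect_equal(summed_variance(toy), var(toy[, 1]) + var(toy[, 2]) +
                 var(toy[, 3]))
  set.seed(16)
  M <- matrix(rnorm(60), 20, 3)
  expect_equal(summed_variance(M), sum(pca_synergies(M)$variances),
               tolerance = 1e-10)
  expect_error(summed_variance(M[1, , drop = FALSE]), "at least 2")
})

test_that("performance curves average test distances per block and flag empty blocks", {
  ses <- clean_human_session("H2", seed = 21, n_blocks = 24)
  # perfect block: endpoints moved onto the targets
  ses$blocks[[3]]$test$x <- ses$blocks[[3]]$test$target_x
  ses$blocks[[3]]$test$y <- ses$blocks[[3]]$test$target_y
  ses$blocks[[3]]$test$distance <- 0
  # all-missing block
  ses$blocks[[4]]$test$missing <- TRUE
  ses$blocks[[4]]$test[, c("q1", "q2", "q3", "x", "y",
                           "distance")] <- NA_real_
  pf <- performance_curve(ses, geo)
  expect_equal(nrow(pf), 24)
  expect_equal(pf$mean_error[3], 0)
  expect_true(is.na(pf$mean_error[4]))
  expect_equal(pf$n_trials[4], 0)
  expect_equal(pf$baseline[1],
               baseline_error(geo$home_H2, geo$test_targets))
  # untrained agent: block-1 error equals the no-movement baseline
  fit <- goal_babbling("H1", config = gb_config(eta = 0, sigma = 0,
                                                n_blocks = 1), seed = 1)
  pf2 <- performance_curve(fit$session, geo)
  expect_equal(pf2$mean_error[1], pf2$baseline[1])
})

test_that("task-space organization does not transfer to finger space under random mappings", {
  # identity mappings: the two spaces are the same up to a uniform
  # linear rescaling, so variance fractions coincide
  pop_id <- generate_population(4, seed = 6)
  for (i in seq_along(pop_id$sessions))
    pop_id$sessions[[i]]$mapping <- c(1L, 2L, 3L)
  mv_id <- morphology_vs_task_pca(pop_id, 3, geo)
  for (w in unique(mv_id$window)) {
    a <- mv_id$variance_fraction[mv_id$window == w & mv_id$space == "task"]
    b <- mv_id$variance_fraction[mv_id$window == w & mv_id$space == "fingers"]
    expect_equal(a, b, tolerance = 1e-10)
  }
  # randomized mappings: consolidation shows in task space only
  pop <- generate_population(6, seed = 7)
  mv <- morphology_vs_task_pca(pop, 3, geo)
  pc12 <- function(sp, w) sum(mv$variance_fraction[mv$space == sp &
                                                     mv$window == w &
                                                     mv$pc <= 2])
  n_win <- max(mv$window)
  expect_gt(pc12("task", n_win), pc12("task", 1))
  fingers <- sapply(seq_len(n_win), pc12, sp = "fingers")
  expect_lt(max(fingers) / min(fingers) - 1, 0.1)
  # bookkeeping: pooled rows are the sum over participants
  rows_w1 <- sum(sapply(pop$sessions, function(s)
    nrow(goalbabbling:::session_test_postures(s, 1:3))))
  expect_equal(unique(mv$n_rows[mv$window == 1]), rows_w1)
})
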