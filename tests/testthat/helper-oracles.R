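# Independent oracles used across test files. These deliberately avoid the
# package's own vectorized implementations: scalar term-by-term sums,
# finite differences, explicit enumerations.

# endpoint by explicit term-by-term trigonometric sums
fk_oracle <- function(q, l = c(0.55, 0.225, 0.225)) {
  x <- l[1] * cos(q[1]) +
    l[2] * cos(q[1] + q[2]) +
    l[3] * cos(q[1] + q[2] + q[3])
  y <- l[1] * sin(q[1]) +
    l[2] * sin(q[1] + q[2]) +
    l[3] * sin(q[1] + q[2] + q[3])
  c(x, y)
}

# central-difference Jacobian of the forward kinematics
num_jacobian <- function(q, h = 1e-6) {
  J <- matrix(0, 2, 3)
  for (i in 1:3) {
    qp <- q; qm <- q
    qp[i] <- qp[i] + h; qm[i] <- qm[i] - h
    J[, i] <- (fk_oracle(qp) - fk_oracle(qm)) / (2 * h)
  }
  J
}

# random rotation matrix in 3D (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# complete synthetic human session with no noise schedules switched off
# unless asked: convenience for windowing tests
clean_human_session <- function(condition = "H1", seed = 1,
                                missing_prob = 0, n_blocks = 24) {
  set.seed(seed)
  generate_session(human_params(condition, missing_prob = missing_prob,
                                n_blocks = n_blocks))
}

# explicit mean-decomposition sums for the two-way repeated-measures
# design: every sum of squares from nested loops over the cell means
rm_anova_oracle <- function(d) {
  us <- sort(unique(d$unit)); as <- sort(unique(d$time))
  bs <- sort(unique(d$condition))
  n <- length(us); a <- length(as); b <- length(bs)
  cell <- function(u, t, c_) mean(d$value[d$unit == u & d$time == t &
                                            d$condition == c_])
  Y <- array(0, c(n, a, b))
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    Y[i, j, k] <- cell(us[i], as[j], bs[k])
  m <- mean(Y)
  ss_a <- 0; ss_b <- 0; ss_ab <- 0; ss_ua <- 0; ss_ub <- 0; ss_tot <- 0
  ss_u <- 0
  for (j in 1:a) ss_a <- ss_a + n * b * (mean(Y[, j, ]) - m)^2
  for (k in 1:b) ss_b <- ss_b + n * a * (mean(Y[, , k]) - m)^2
  for (i in 1:n) ss_u <- ss_u + a * b * (mean(Y[i, , ]) - m)^2
  for (j in 1:a) for (k in 1:b)
    ss_ab <- ss_ab + n * (mean(Y[, j, k]) - mean(Y[, j, ]) -
                            mean(Y[, , k]) + m)^2
  for (i in 1:n) for (j in 1:a)
    ss_ua <- ss_ua + b * (mean(Y[i, j, ]) - mean(Y[i, , ]) -
                            mean(Y[, j, ]) + m)^2
  for (i in 1:n) for (k in 1:b)
    ss_ub <- ss_ub + a * (mean(Y[i, , k]) - mean(Y[i, , ]) -
                            mean(Y[, , k]) + m)^2
  for (i in 1:n) for (j in 1:a) for (k in 1:b)
    ss_tot <- ss_tot + (Y[i, j, k] - m)^2
  ss_uab <- ss_tot - ss_u - ss_a - ss_b - ss_ab - ss_ua - ss_ub
  list(
    F_time = (ss_a / (a - 1)) / (ss_ua / ((a - 1) * (n - 1))),
    F_cond = (ss_b / (b - 1)) / (ss_ub / ((b - 1) * (n - 1))),
    F_int = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_uab / ((a - 1) * (b - 1) * (n - 1))),
    pes_time = ss_a / (ss_a + ss_ua),
    pes_cond = ss_b / (ss_b + ss_ub),
    pes_int = ss_ab / (ss_ab + ss_uab))
}

# random balanced long-format design
random_rm_design <- function(n_units = 6, a = 3, b = 2) {
  d <- expand.grid(unit = seq_len(n_units), time = seq_len(a),
                   condition = seq_len(b))
  d$value <- rnorm(nrow(d))
  d
}

# exhaustive sign-assignment enumeration for the signed-rank test
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# rank-arithmetic Friedman statistic (no tie correction shortcut: the
# generic tie-corrected form written out directly)
friedman_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}
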