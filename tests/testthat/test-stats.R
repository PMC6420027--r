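test_that("the repeated-measures ANOVA matches explicit sum-of-squares decomposition", {
  set.seed(30)
  # 4 units x 2 times x 2 conditions toy table
  d <- random_rm_design(4, 2, 2)
  fit <- rm_anova_2way(d)
  or <- rm_anova_oracle(d)
  expect_equal(fit$F, c(or$F_time, or$F_cond, or$F_int), tolerance = 1e-10)
  expect_equal(fit$pes, c(or$pes_time, or$pes_cond, or$pes_int),
               tolerance = 1e-10)
  # randomized balanced designs, property sweep
  for (rep in 1:8) {
    d <- random_rm_design(sample(4:8, 1), sample(2:5, 1), 2)
    fit <- rm_anova_2way(d)
    or <- rm_anova_oracle(d)
    expect_equal(fit$F, c(or$F_time, or$F_cond, or$F_int),
                 tolerance = 1e-8)
  }
})

test_that("the rmANOVA agrees with aov error strata and is affine-invariant", {
  set.seed(31)
  d <- random_rm_design(6, 4, 2)
  fit <- rm_anova_2way(d)
  a <- summary(stats::aov(value ~ factor(time) * factor(condition) +
                            Error(factor(unit) /
                                    (factor(time) * factor(condition))),
                          data = d))
  f_aov <- c(a[["Error: factor(unit):factor(time)"]][[1]]["F value"][1, ],
             a[["Error: factor(unit):factor(condition)"]][[1]]["F value"][1, ],
             a[["Error: factor(unit):factor(time):factor(condition)"]][[1]][
               "F value"][1, ])
  expect_equal(fit$F, unname(unlist(f_aov)), tolerance = 1e-8)
  # location and scale changes leave F and partial eta-squared unchanged
  d2 <- d; d2$value <- 3.7 * d2$value + 100
  fit2 <- rm_anova_2way(d2)
  expect_equal(fit2$F, fit$F, tolerance = 1e-8)
  expect_equal(fit2$pes, fit$pes, tolerance = 1e-8)
  # constant response: no variance to test
  d3 <- d; d3$value <- 5
  expect_error(rm_anova_2way(d3), "degenerate")
  # incomplete unit is dropped listwise
  d4 <- d[!(d$unit == 1 & d$time == 2), ]
  expect_message(fit4 <- rm_anova_2way(d4), "listwise")
  expect_equal(fit4$df_error[1], (4 - 1) * (5 - 1))
})

test_that("the exact sign test reproduces binomial tail probabilities", {
  expect_equal(sign_test(rep(1, 5))$p, 0.0625)
  expect_equal(sign_test(c(rep(1, 5), rep(-1, 5)))$p, 1)
  # 28 positive of 40: enumeration of the binomial tails
  d <- c(rep(1, 28), rep(-1, 12))
  p_oracle <- 2 * sum(dbinom(28:40, 40, 0.5))
  expect_equal(sign_test(d)$p, p_oracle, tolerance = 1e-12)
  expect_equal(sign_test(d)$p, binom.test(28, 40)$p.value,
               tolerance = 1e-12)
  # zeros are dropped
  expect_equal(sign_test(c(0, 0, rep(1, 5)))$n, 5)
  expect_error(sign_test(c(0, 0)), "zero")
})

test_that("the signed-rank test matches exhaustive enumeration and the normal reference", {
  set.seed(32)
  # n = 6: exact enumeration over all 2^6 sign assignments
  d <- c(1.5, -0.3, 2.2, 0.7, -1.1, 0.4)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_enum_oracle(d),
               tolerance = 1e-12)
  d_ties <- c(1, -1, 2, 2, -3, 4, 0.5)
  expect_equal(wilcoxon_signed_rank(d_ties)$p,
               wilcoxon_enum_oracle(d_ties), tolerance = 1e-12)
  # antisymmetric sample: centred statistic, z = 0
  d_anti <- c(seq(0.1, 1.3, by = 0.1), -seq(0.1, 1.3, by = 0.1))
  expect_equal(wilcoxon_signed_rank(d_anti)$z, 0)
  # negating differences flips z, keeps p
  d_big <- rnorm(25) + 0.4
  w1 <- wilcoxon_signed_rank(d_big)
  w2 <- wilcoxon_signed_rank(-d_big)
  expect_equal(w1$z, -w2$z, tolerance = 1e-12)
  expect_equal(w1$p, w2$p, tolerance = 1e-12)
  # normal branch agrees with the standard implementation
  ref <- wilcox.test(d_big, exact = FALSE, correct = TRUE)
  expect_equal(w1$p, ref$p.value, tolerance = 1e-10)
})

test_that("the Friedman statistic equals rank arithmetic and is label-invariant", {
  m <- rbind(c(1.2, 0.7, 2.0), c(0.4, 0.5, 1.1), c(2.2, 1.0, 2.5))
  fr <- friedman_test(m)
  expect_equal(fr$chisq, friedman_oracle(m), tolerance = 1e-12)
  ref <- friedman.test(m)
  expect_equal(fr$chisq, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(fr$p, ref$p.value, tolerance = 1e-10)
  # identical within-row orderings up to row offsets: no evidence
  m0 <- outer(c(0, 5, 9), c(1, 1, 1)) + rep(c(0.3, 0.3, 0.3), each = 3)
  expect_equal(friedman_test(m0)$chisq, 0)
  expect_equal(friedman_test(m0)$p, 1)
  # permuting columns identically in every row preserves the statistic
  set.seed(33)
  M <- matrix(rnorm(40), 10, 4)
  perm <- sample(4)
  expect_equal(friedman_test(M)$chisq, friedman_test(M[, perm])$chisq,
               tolerance = 1e-12)
  expect_error(friedman_test(M[1, , drop = FALSE]), "at least 2")
})

test_that("all four tests hold their nominal size under a Gaussian null", {
  set.seed(34)
  n_rep <- 1000
  rej <- c(anova_t = 0, sign = 0, wilcoxon = 0, friedman = 0)
  for (r in seq_len(n_rep)) {
    d <- random_rm_design(8, 4, 2)
    rej["anova_t"] <- rej["anova_t"] + (rm_anova_2way(d)$p[1] < 0.05)
    x <- rnorm(20)
    rej["sign"] <- rej["sign"] + (sign_test(x)$p < 0.05)
    rej["wilcoxon"] <- rej["wilcoxon"] + (wilcoxon_signed_rank(x)$p < 0.05)
    rej["friedman"] <- rej["friedman"] +
      (friedman_test(matrix(rnorm(60), 15, 4))$p < 0.05)
  }
  rates <- rej / n_rep
  expect_true(all(rates >= 0.03 & rates <= 0.07),
              info = paste(names(rates), round(rates, 3), collapse = ", "))
})
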