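#' Two-way repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for a fully within-unit
#' two-factor design (factors Time and Condition, units crossed with
#' both). Each effect is tested against its own unit-interaction error
#' term: F(Time) = MS_Time / MS_{Time x Unit}, and analogously for
#' Condition and the interaction. Partial eta-squared is
#' SS_effect / (SS_effect + SS_error). In the study design the unit is
#' the finger mapping (each mapping occurs once per condition), not the
#' participant. No sphericity correction is applied by default;
#' \code{gg_correction = TRUE} applies Greenhouse-Geisser-adjusted
#' degrees of freedom to the Time and interaction tests.
#'
#' Units with incomplete cells are removed (listwise deletion) with a
#' message; replicate observations within a cell are averaged.
#'
#' @param data Long-format data frame.
#' @param value,unit,time,condition Column names.
#' @param gg_correction Apply Greenhouse-Geisser correction.
#' @return Object of class \code{"rm_anova"}: a data frame with one row
#'   per effect (Time, Condition, Time:Condition): \code{ss}, \code{df},
#'   \code{ms}, \code{ss_error}, \code{df_error}, \code{F}, \code{p},
#'   \code{pes} (partial eta-squared).
#' @export
rm_anova_2way <- function(data, value = "value", unit = "unit",
                          time = "time", condition = "condition",
                          gg_correction = FALSE) {
  d <- data.frame(y = data[[value]], u = factor(data[[unit]]),
                  a = factor(data[[time]]), b = factor(data[[condition]]))
  d <- d[stats::complete.cases(d), ]
  # average replicates, then require complete crossing per unit
  d <- stats::aggregate(y ~ u + a + b, data = d, FUN = mean)
  full <- nlevels(d$a) * nlevels(d$b)
  cnt <- table(d$u)
  keep <- names(cnt)[cnt == full]
  if (length(keep) < length(cnt))
    message("dropping ", length(cnt) - length(keep),
            " incomplete unit(s) (listwise deletion)")
  d <- d[d$u %in% keep, ]
  d$u <- droplevels(d$u)
  n <- nlevels(d$u); a <- nlevels(d$a); b <- nlevels(d$b)
  if (n < 2 || a < 2 || b < 2)
    stop("design needs at least 2 units and 2 levels per factor")
  Y <- array(0, c(n, a, b))
  Y[cbind(as.integer(d$u), as.integer(d$a), as.integer(d$b))] <- d$y
  m <- mean(Y)
  m_u <- apply(Y, 1, mean); m_a <- apply(Y, 2, mean); m_b <- apply(Y, 3, mean)
  m_ua <- apply(Y, c(1, 2), mean); m_ub <- apply(Y, c(1, 3), mean)
  m_ab <- apply(Y, c(2, 3), mean)
  ss_total <- sum((Y - m)^2)
  ss_u <- a * b * sum((m_u - m)^2)
  ss_a <- n * b * sum((m_a - m)^2)
  ss_b <- n * a * sum((m_b - m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + m)^2)
  ss_ua <- b * sum((m_ua - outer(m_u, rep(1, a)) -
                      outer(rep(1, n), m_a) + m)^2)
  ss_ub <- a * sum((m_ub - outer(m_u, rep(1, b)) -
                      outer(rep(1, n), m_b) + m)^2)
  ss_uab <- ss_total - ss_u - ss_a - ss_b - ss_ab - ss_ua - ss_ub
  eff <- data.frame(
    effect = c("Time", "Condition", "Time:Condition"),
    ss = c(ss_a, ss_b, ss_ab),
    df = c(a - 1, b - 1, (a - 1) * (b - 1)),
    ss_error = c(ss_ua, ss_ub, ss_uab),
    df_error = c((a - 1) * (n - 1), (b - 1) * (n - 1),
                 (a - 1) * (b - 1) * (n - 1)))
  if (any(eff$ss_error <= 1e-300))
    stop("degenerate design: zero error sum of squares")
  eff$ms <- eff$ss / eff$df
  eff$F <- eff$ms / (eff$ss_error / eff$df_error)
  eps <- c(1, 1, 1)
  if (gg_correction) {
    eps[1] <- .gg_epsilon(m_ua)
    eps[3] <- eps[1]
  }
  eff$p <- stats::pf(eff$F, eff$df * eps, eff$df_error * eps,
                     lower.tail = FALSE)
  eff$pes <- eff$ss / (eff$ss + eff$ss_error)
  structure(eff[, c("effect", "ss", "df", "ms", "F", "p", "pes",
                    "ss_error", "df_error")],
            class = c("rm_anova", "data.frame"))
}

# Greenhouse-Geisser epsilon from the units x time-levels matrix
.gg_epsilon <- function(M) {
  S <- stats::cov(M)
  k <- ncol(S)
  num <- (sum(diag(S)) - k * mean(S))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * mean(S)^2)
  max(1 / (k - 1), min(1, num / den))
}

#' @export
print.rm_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, 5); y$ms <- signif(y$ms, 5)
  y$F <- round(y$F, 2); y$p <- signif(y$p, 3); y$pes <- round(y$pes, 3)
  print(y[, c("effect", "ss", "df", "ms", "F", "p", "pes")],
        row.names = FALSE)
  invisible(x)
}

#' Exact sign test
#'
#' Two-sided exact binomial test on the signs of paired differences;
#' zero differences are dropped. p = min(1, 2 min(P(X <= k), P(X >= k)))
#' with X ~ Binomial(n, 1/2).
#'
#' @param differences Numeric vector of paired differences.
#' @return List: \code{n} (nonzero pairs), \code{n_positive}, \code{p}.
#' @export
sign_test <- function(differences) {
  d <- differences[!is.na(differences) & differences != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  k <- sum(d > 0)
  p <- min(1, 2 * min(stats::pbinom(k, n, 0.5),
                      stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)))
  list(n = n, n_positive = k, p = p)
}

# exact null distribution of the positive-rank sum W+ for given |d| ranks,
# by convolution over sign assignments (handles midranks)
.wilcox_exact_dist <- function(ranks) {
  tot <- sum(ranks)
  # distribution over 2*W+ to keep integer indexing with midranks (.5)
  f <- numeric(2 * tot + 1); f[1] <- 1
  for (r in ranks) {
    g <- numeric(length(f))
    shift <- round(2 * r)
    g[(shift + 1):length(f)] <- f[1:(length(f) - shift)]
    f <- f + g
  }
  f / sum(f)
}

#' Wilcoxon signed-rank test
#'
#' Paired test on the median difference. Zeros are dropped and ties
#' receive midranks. For n <= 12 nonzero pairs the p-value is exact
#' (enumeration of all sign assignments via convolution); otherwise a
#' normal approximation with tie-corrected variance and a 0.5 continuity
#' correction towards the mean is used, reporting the signed z.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List: \code{n}, \code{W} (positive-rank sum), \code{z}
#'   (NA in the exact branch), \code{p}, \code{method}.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 12) {
  d <- differences[!is.na(differences) & differences != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    f <- .wilcox_exact_dist(r)
    w2 <- round(2 * W)
    dev <- abs(w2 - 2 * mu)
    support <- seq_along(f) - 1
    p <- sum(f[abs(support - 2 * mu) >= dev - 1e-9])
    return(list(n = n, W = W, z = NA_real_, p = min(1, p),
                method = "exact"))
  }
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5 * sign(W - mu)
  z <- if (v > 0) (W - mu - cc) / sqrt(v) else 0
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(n = n, W = W, z = z, p = min(1, p), method = "normal")
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric test for a Time effect: values are ranked within each
#' unit (ties midranked) and the tie-corrected Friedman chi-square is
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param mat Matrix, units in rows, repeated levels in columns.
#' @return List: \code{chisq}, \code{df}, \code{p}, \code{n}, \code{k}.
#' @export
friedman_test <- function(mat) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop("need at least 2 units and 2 levels")
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  denom <- A - C
  if (denom <= 0) return(list(chisq = 0, df = k - 1, p = 1, n = n, k = k))
  chisq <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4) / denom
  list(chisq = chisq, df = k - 1,
       p = stats::pchisq(chisq, k - 1, lower.tail = FALSE), n = n, k = k)
}
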