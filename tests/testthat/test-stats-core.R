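# Statistics engine: mixed ANOVA, t-tests, Mann-Whitney, FDR, chi-square,
# outlier screen, power.

make_balanced_222 <- function(n_per_cell, effects = c(0, 0, 0)) {
  wide <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                      rep = seq_len(n_per_cell))
  wide$y1 <- rnorm(nrow(wide))
  wide$y2 <- wide$y1 * 0.5 + rnorm(nrow(wide)) +
    effects[1] * (wide$a == "a2") + effects[2] * (wide$b == "b2") +
    effects[3] * (wide$a == "a2") * (wide$b == "b2")
  wide$id <- sprintf("S%03d", seq_len(nrow(wide)))
  wide
}

long_from_wide <- function(wide) {
  data.frame(id = rep(wide$id, 2), a = rep(wide$a, 2), b = rep(wide$b, 2),
             session = rep(c("pre", "post"), each = nrow(wide)),
             y = c(wide$y1, wide$y2))
}

test_that("mixed ANOVA gives zero F when all cell means are equal", {
  wide <- expand.grid(rep = 1:4, a = c("a1", "a2"), b = c("b1", "b2"))
  # every cell mean is 0 at both sessions; subjects still vary
  wide$y1 <- c(-1, 1, -1, 1)[wide$rep]
  wide$y2 <- c(-1, 1, 1, -1)[wide$rep]
  wide$id <- sprintf("S%d", seq_len(nrow(wide)))
  res <- mixed_anova(long_from_wide(wide),
                     dv = "y", subject = "id", within = "session",
                     between = c("a", "b"))
  expect_true(all(abs(res$F) < 1e-20))
  expect_true(all(res$eta_p_sq < 1e-20))
})

test_that("mixed ANOVA matches the closed-form cell-means oracle on balanced data", {
  set.seed(301)
  for (r in 1:12) {
    wide <- make_balanced_222(n_per_cell = sample(3:6, 1),
                              effects = rnorm(3))
    res <- mixed_anova(long_from_wide(wide), dv = "y", subject = "id",
                       within = "session", between = c("a", "b"))
    orc <- oracle_mixed_222(wide)
    map <- c(a = "a", b = "b", `a:b` = "a:b", session = "w",
             `a:session` = "a:w", `b:session` = "b:w",
             `a:b:session` = "a:b:w")
    for (eff in res$effect) {
      expect_equal(res$F[res$effect == eff],
                   orc$F[orc$effect == map[[eff]]], tolerance = 1e-8)
    }
    # partial eta squared self-consistency with F and dfs
    expect_equal(res$eta_p_sq,
                 res$F * res$df1 / (res$F * res$df1 + res$df2),
                 tolerance = 1e-10)
  }
})

test_that("ANOVA sums of squares are additive on balanced data", {
  set.seed(302)
  wide <- make_balanced_222(5, effects = c(0.5, -0.3, 0.8))
  orc <- oracle_mixed_222(wide)
  y <- c(wide$y1, wide$y2)
  ss_total <- sum((y - mean(y))^2)
  ss_parts <- sum(orc$ss) + orc$ss_err[1] + orc$ss_err[4]
  expect_equal(ss_parts / ss_total, 1, tolerance = 1e-8)
})

test_that("mixed ANOVA drops incomplete subjects and rejects tiny cells", {
  set.seed(303)
  wide <- make_balanced_222(4)
  long <- long_from_wide(wide)
  long <- long[!(long$id == wide$id[1] & long$session == "post"), ]
  res <- mixed_anova(long, dv = "y", subject = "id", within = "session",
                     between = c("a", "b"))
  expect_identical(attr(res, "dropped"), wide$id[1])
  expect_identical(attr(res, "n"), nrow(wide) - 1L)
  tiny <- long_from_wide(make_balanced_222(1))
  expect_error(mixed_anova(tiny, dv = "y", subject = "id",
                           within = "session", between = c("a", "b")),
               "at least two")
})

test_that("pooled t-test and Hedges' g match the textbook formulas", {
  set.seed(304)
  x <- rnorm(32); y <- rnorm(34, 0.4)
  res <- t_test_g(x, y)
  orc <- oracle_t_pooled(x, y)
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_identical(res$df, 64L)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  expect_equal(res$g, orc$g, tolerance = 1e-12)
  res0 <- t_test_g(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(res0$t, 0)
  expect_equal(res0$g, 0)
  # paired version equals the one-sample formula on differences
  a <- rnorm(15); b <- rnorm(15, 0.5)
  rp <- t_test_g(a, b, paired = TRUE)
  d <- a - b
  expect_equal(rp$t, mean(d) / (sd(d) / sqrt(15)), tolerance = 1e-12)
  expect_equal(rp$g, (1 - 3 / (4 * 14 - 1)) * mean(d) / sd(d),
               tolerance = 1e-12)
  expect_error(t_test_g(rep(1, 5), rep(1, 5)), "zero pooled variance")
})

test_that("Mann-Whitney U handles the degenerate orderings", {
  res <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12, 13))
  expect_equal(res$U, 0)
  x <- c(1, 2, 3)
  res2 <- mann_whitney_u(x, x)
  expect_equal(res2$U, length(x)^2 / 2)
  expect_gt(res2$p, 0.9)
})

test_that("exact Mann-Whitney p equals full enumeration for all n1, n2 <= 6", {
  set.seed(305)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      vals <- sample(seq_len(100), n1 + n2)  # distinct -> no ties
      x <- vals[seq_len(n1)]
      y <- vals[-seq_len(n1)]
      res <- mann_whitney_u(x, y)
      orc <- oracle_mw_exact(x, y)
      expect_equal(res$U, orc$U)
      expect_equal(res$p, orc$p, tolerance = 1e-12)
      expect_identical(res$method, "exact")
    }
  }
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(306)
  for (r in 1:50) {
    p <- runif(sample(3:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
  }
})

test_that("chi-square matches the expected-counts formula", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_lt(chi_square_independence(prop)$chi2, 1e-12)
  set.seed(307)
  for (r in 1:20) {
    tab <- matrix(rpois(8, 20) + 1, 2)
    res <- chi_square_independence(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - expected)^2 / expected),
                 tolerance = 1e-12)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
  }
  expect_error(chi_square_independence(matrix(c(0, 0, 5, 3), 2,
                                              byrow = TRUE)),
               "zero marginal")
})

test_that("a 2x4 completion table yields a df-3 Pearson statistic", {
  # reconstructed assigned/dropped counts from the reported per-group rates
  tab <- rbind(completed = c(17, 18, 18, 18), dropped = c(3, 3, 0, 2))
  res <- chi_square_independence(tab)
  expect_equal(res$df, 3)
  expect_true(is.finite(res$chi2) && res$chi2 > 0)
})

test_that("extreme outliers use the 3-IQR fences with interpolated quartiles", {
  vals <- c(1:20, 1000)
  res <- extreme_outliers(vals)
  expect_identical(res$indices, 21L)
  expect_identical(extreme_outliers(rep(5, 10))$indices, integer(0))
  set.seed(308)
  for (r in 1:20) {
    v <- rt(30, df = 2)
    res <- extreme_outliers(v)
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    lo <- q[1] - 3 * (q[2] - q[1])
    hi <- q[2] + 3 * (q[2] - q[1])
    expect_identical(res$indices, which(v < lo | v > hi))
  }
})

test_that("power-based N satisfies the noncentral-F definition minimally", {
  power_oracle <- function(N, eta, alpha = 0.05, m = 2, rho = 0.5,
                           groups = 2) {
    f2 <- eta / (1 - eta)
    lambda <- f2 * N * m / (1 - rho)
    1 - pf(qf(1 - alpha, 1, N - groups), 1, N - groups, ncp = lambda)
  }
  expect_identical(rm_power_sample_size(0.06, power = 1e-6), 4L)
  N <- rm_power_sample_size(0.06, alpha = 0.05, power = 0.80)
  expect_gte(power_oracle(N, 0.06), 0.80)
  expect_lt(power_oracle(N - 2, 0.06), 0.80)
  expect_true(N >= 28 && N <= 36)
  for (eta in c(0.03, 0.10, 0.25)) {
    N <- rm_power_sample_size(eta, power = 0.9)
    expect_gte(power_oracle(N, eta), 0.9)
    expect_lt(power_oracle(N - 2, eta), 0.9)
  }
})
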