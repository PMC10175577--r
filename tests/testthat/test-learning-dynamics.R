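# Learning-curve analysis: smoothing, spline fits, knot search, group
# comparison, sequential contrasts.

test_that("smoothing produces the 15 adjacent-pair means", {
  expect_equal(smooth_series(rep(3, 16)), rep(3, 15))
  expect_equal(smooth_series(1:16), seq(1.5, 15.5, 1))
  set.seed(401)
  for (r in 1:20) {
    raw <- rnorm(16)
    conv <- as.numeric(stats::filter(raw, c(0.5, 0.5), sides = 1))[-1]
    expect_equal(smooth_series(raw), conv)
  }
  expect_error(smooth_series(1:15), "exactly 16")
  expect_error(smooth_series(c(1:15, NA)), "exactly 16")
})

test_that("spline fits recover exact piecewise-linear data", {
  v <- 1 + 0.5 * pmin(1:15, 8)
  f <- fit_spline_at_knot(v, 8)
  expect_equal(f$slope1, 0.5, tolerance = 1e-10)
  expect_equal(f$slope2, 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # nested model: purely linear data fit perfectly at any knot
  lin <- 2 + 0.3 * (1:15)
  for (k in c(2, 7, 14)) {
    fl <- fit_spline_at_knot(lin, k)
    expect_equal(fl$slope1, 0.3, tolerance = 1e-9)
    expect_equal(fl$slope2, 0.3, tolerance = 1e-9)
    expect_equal(fl$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("spline coefficients equal the explicit normal-equations solution", {
  set.seed(402)
  for (r in 1:20) {
    v <- rnorm(15)
    for (k in 2:14) {
      f <- fit_spline_at_knot(v, k)
      beta <- oracle_spline_coef(v, k)
      expect_equal(f$intercept, beta[1], tolerance = 1e-8)
      expect_equal(f$slope1, beta[2], tolerance = 1e-8)
      expect_equal(f$slope2, beta[2] + beta[3], tolerance = 1e-8)
    }
  }
})

test_that("flat series are flagged degenerate", {
  f <- fit_spline_at_knot(rep(2, 15), 5)
  expect_true(f$degenerate)
  expect_true(is.na(f$r_squared))
  expect_equal(f$slope1, 0)
  b <- select_best_knot(rep(2, 15))
  expect_true(b$degenerate)
  expect_true(is.na(b$knot_index))
})

test_that("knot search picks the programmed knot and breaks ties low", {
  for (k in 3:13) {
    v <- 1 + 0.4 * pmin(1:15, k)
    expect_identical(select_best_knot(v)$knot_index, k)
  }
  # linear data tie across all knots resolves to the smallest
  expect_identical(select_best_knot(2 + 0.3 * (1:15))$knot_index, 2L)
})

test_that("knot search equals the argmax over all 13 single-knot fits", {
  set.seed(403)
  for (r in 1:300) {
    v <- 1 + 0.2 * pmin(1:15, sample(3:12, 1)) + rnorm(15, 0, 0.2)
    r2 <- vapply(2:14, function(k) {
      beta <- oracle_spline_coef(v, k)
      fitted <- cbind(1, 1:15, pmax(0, (1:15) - k)) %*% beta
      1 - sum((v - fitted)^2) / sum((v - mean(v))^2)
    }, numeric(1))
    expect_identical(select_best_knot(v)$knot_index,
                     (2:14)[which.max(r2)])
  }
})

test_that("knot selection is invariant to affine rescaling", {
  set.seed(404)
  for (r in 1:30) {
    v <- 1 + 0.3 * pmin(1:15, 9) + rnorm(15, 0, 0.3)
    f <- select_best_knot(v)
    f2 <- select_best_knot(3 + 2.5 * v)
    expect_identical(f2$knot_index, f$knot_index)
    expect_equal(f2$slope1, 2.5 * f$slope1, tolerance = 1e-8)
    expect_equal(f2$r_squared, f$r_squared, tolerance = 1e-8)
  }
})

test_that("the estimator recovers programmed knots and slopes from noisy series", {
  # study-scale noise (engine session-to-session SD ~0.15), n = 30 per cell
  set.seed(405)
  for (k in c(5, 8, 11)) {
    for (s in c(0.1, 0.2)) {
      knots <- numeric(30)
      slopes <- numeric(30)
      for (i in 1:30) {
        v <- 1.5 + s * pmin(1:15, k) + rnorm(15, 0, 0.15)
        f <- select_best_knot(v)
        knots[i] <- f$knot_index
        slopes[i] <- f$slope1
      }
      expect_lte(abs(median(knots) - k), 1)
      expect_lte(abs(median(slopes) - s) / s, 0.25)
    }
  }
})

test_that("identical groups give the null Mann-Whitney comparison", {
  set.seed(406)
  fits <- lapply(1:8, function(i) {
    select_best_knot(1 + 0.2 * pmin(1:15, 8) + rnorm(15, 0, 0.2))
  })
  cmp <- compare_learning_parameters(fits, fits)
  expect_equal(cmp$U, rep(8 * 8 / 2, 2))
  expect_true(all(cmp$p > 0.9))
  expect_equal(cmp$g, c(0, 0))
  expect_identical(cmp$measure, c("first_slope", "knot_location"))
  expect_error(compare_learning_parameters(fits[1], fits), "at least two")
})

test_that("sequential contrasts are null when session changes cancel exactly", {
  # per-subject change from S1 is +/-0.1, balanced within each group, so the
  # session and interaction effects are exactly zero while error variance
  # stays positive
  base <- rep(seq(1, 4, length.out = 10), 2)
  delta <- rep(c(0.1, -0.1), 10)
  sessions <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(id = sprintf("P%02d", i),
               group = ifelse(i <= 10, "distributed", "intensive"),
               session = 1:16,
               outcome = base[i] + delta[i] * (1:16 > 1))
  }))
  res <- sequential_session_anovas(sessions)
  expect_equal(nrow(res), 45)
  null_rows <- res$effect %in% c("session", "group:session")
  expect_true(all(res$F[null_rows] < 1e-12))
  expect_true(all(res$p_fdr[null_rows] > 0.99))
})

test_that("a gain from session 4 onward is detected from S1-vs-S4 through S16", {
  set.seed(407)
  n <- 17
  make_group <- function(prefix, grp) {
    do.call(rbind, lapply(1:n, function(i) {
      base <- rnorm(1, 2, 0.4)
      gain <- ifelse(1:16 >= 4, 1.0, 0)  # large programmed effect
      data.frame(id = sprintf("%s%02d", prefix, i), group = grp,
                 session = 1:16,
                 outcome = base + gain + rnorm(16, 0, 0.15))
    }))
  }
  sessions <- rbind(make_group("D", "distributed"), make_group("I", "intensive"))
  res <- sequential_session_anovas(sessions)
  sess <- res[res$effect == "session", ]
  sig <- sess$contrast[sess$p_fdr < 0.05]
  expect_true(all(sprintf("S1_vs_S%d", 4:16) %in% sig))
  expect_false(any(sprintf("S1_vs_S%d", 2:3) %in% sig))
})

test_that("FDR correction within each effect family equals the BH oracle", {
  set.seed(408)
  sessions <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(id = sprintf("P%02d", i),
               group = ifelse(i <= 6, "distributed", "intensive"),
               session = 1:16, outcome = rnorm(16, 2, 0.5))
  }))
  res <- sequential_session_anovas(sessions, fdr_family = "per_effect")
  for (e in unique(res$effect)) {
    sel <- res$effect == e
    expect_equal(res$p_fdr[sel], oracle_bh(res$p_raw[sel]), tolerance = 1e-12)
  }
  joint <- sequential_session_anovas(sessions, fdr_family = "joint")
  expect_equal(joint$p_fdr, oracle_bh(joint$p_raw), tolerance = 1e-12)
})
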