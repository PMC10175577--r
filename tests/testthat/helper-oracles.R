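# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (explicit formulas, enumeration, brute force) and
# never calls the package code path it checks.

# brute-force re-check of every block invariant
block_violations <- function(block, config) {
  v <- character(0)
  n <- block$level
  len <- length(block$stimuli)
  if (len != config$critical_screens + n) v <- c(v, "wrong length")
  if (length(block$is_target) != len) v <- c(v, "flag length mismatch")
  if (sum(block$is_target) != config$targets_per_block) v <- c(v, "target count")
  if (any(block$is_target[seq_len(n)])) v <- c(v, "target in seed screens")
  for (i in seq.int(n + 1L, len)) {
    is_rep <- block$stimuli[i] == block$stimuli[i - n]
    if (block$is_target[i] && !is_rep) v <- c(v, paste("target not a repeat at", i))
    if (!block$is_target[i] && is_rep) v <- c(v, paste("non-target repeats at", i))
  }
  if (!all(block$stimuli %in% config$alphabet)) v <- c(v, "stimulus outside alphabet")
  v
}

# closed-form cell-means oracle for a balanced 2 (a) x 2 (b) x 2 (within)
# mixed ANOVA; wide has factors a, b and responses y1, y2, balanced cells
oracle_mixed_222 <- function(wide) {
  n <- nrow(wide)
  stopifnot(length(unique(table(interaction(wide$a, wide$b)))) == 1L)
  y <- c(wide$y1, wide$y2)
  a <- factor(rep(wide$a, 2))
  b <- factor(rep(wide$b, 2))
  w <- factor(rep(c("w1", "w2"), each = n))
  subj <- rep(seq_len(n), 2)
  g <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean); mw <- tapply(y, w, mean)
  mab <- tapply(y, interaction(a, b), mean)
  maw <- tapply(y, interaction(a, w), mean)
  mbw <- tapply(y, interaction(b, w), mean)
  mabw <- tapply(y, interaction(a, b, w), mean)
  msub <- tapply(y, subj, mean)
  SS_A <- n * sum((ma - g)^2)
  SS_B <- n * sum((mb - g)^2)
  SS_W <- n * sum((mw - g)^2)
  SS_AB <- (n / 2) * sum((mab - rep(ma, times = 2) - rep(mb, each = 2) + g)^2)
  SS_AW <- (n / 2) * sum((maw - rep(ma, times = 2) - rep(mw, each = 2) + g)^2)
  SS_BW <- (n / 2) * sum((mbw - rep(mb, times = 2) - rep(mw, each = 2) + g)^2)
  # three-way deviation computed elementwise to stay explicit
  lv_a <- levels(a); lv_b <- levels(b); lv_w <- levels(w)
  SS_ABW <- 0
  for (ia in lv_a) for (ib in lv_b) for (iw in lv_w) {
    m3 <- mean(y[a == ia & b == ib & w == iw])
    dev <- m3 - mab[paste(ia, ib, sep = ".")] - maw[paste(ia, iw, sep = ".")] -
      mbw[paste(ib, iw, sep = ".")] + ma[ia] + mb[ib] + mw[iw] - g
    SS_ABW <- SS_ABW + (n / 4) * dev^2
  }
  cell_of <- interaction(wide$a, wide$b)
  SS_subj <- 2 * sum((msub - mab[as.character(cell_of)])^2)
  SS_tot <- sum((y - g)^2)
  SS_werr <- SS_tot - (SS_A + SS_B + SS_AB + SS_W + SS_AW + SS_BW +
                         SS_ABW + SS_subj)
  df_err <- n - 4
  ms_subj <- SS_subj / df_err
  ms_werr <- SS_werr / df_err
  data.frame(
    effect = c("a", "b", "a:b", "w", "a:w", "b:w", "a:b:w"),
    F = c(SS_A / ms_subj, SS_B / ms_subj, SS_AB / ms_subj,
          SS_W / ms_werr, SS_AW / ms_werr, SS_BW / ms_werr,
          SS_ABW / ms_werr),
    ss = c(SS_A, SS_B, SS_AB, SS_W, SS_AW, SS_BW, SS_ABW),
    ss_err = c(rep(SS_subj, 3), rep(SS_werr, 4)),
    df2 = df_err
  )
}

# literal Benjamini-Hochberg step-up: adj_p(i) = min_{j >= i} (m * p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney U and exact two-sided p by full enumeration (no ties)
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  U <- sum(outer(x, y, ">"))
  stopifnot(!anyDuplicated(c(x, y)))
  combined <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  U0 <- apply(idx, 2, function(ii) {
    sum(outer(combined[ii], combined[-ii], ">"))
  })
  p_low <- mean(U0 <= U)
  p_high <- mean(U0 >= U)
  list(U = U, p = min(1, 2 * min(p_low, p_high)))
}

# digit-span oracle: administer the protocol literally from a full table of
# per-length trial outcomes, then apply the 50%-of-trials definition
oracle_span <- function(c1, c2, lengths) {
  administered <- integer(0)
  passed <- logical(0)
  for (i in seq_along(lengths)) {
    administered <- c(administered, lengths[i])
    ok <- c1[i] || c2[i]
    passed <- c(passed, ok)
    if (!ok) break
  }
  if (any(passed)) max(administered[passed]) else min(lengths) - 1L
}

# pooled-variance t and Hedges' g from textbook formulas
oracle_t_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t), df)
  g <- (1 - 3 / (4 * df - 1)) * (mean(x) - mean(y)) / sqrt(sp2)
  list(t = t, df = df, p = p, g = g)
}

# one-knot spline coefficients by explicit 3x3 normal equations
oracle_spline_coef <- function(values, k) {
  t <- seq_along(values)
  X <- cbind(1, t, pmax(0, t - k))
  solve(t(X) %*% X, t(X) %*% values)
}

# tiny WMT-only recovery cohort: every learner shares programmed knot/slope
make_recovery_fits <- function(knot, slope, n, config = cohort_config(),
                               task_cfg = nback_config("verbal")) {
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    base <- max(1, rnorm(1, config$learner$baseline_mean,
                         config$learner$baseline_sd))
    lp <- learner_params(baseline = base, slope1 = slope, knot_session = knot,
                         discrim = config$learner$discrim,
                         lapse = config$learner$lapse)
    raw <- vapply(1:16, function(t) {
      run_session(responder_logistic(capacity_at(lp, t), lp$discrim,
                                     lp$lapse), task_cfg)$outcome
    }, numeric(1))
    fits[[i]] <- select_best_knot(smooth_series(raw))
  }
  fits
}
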