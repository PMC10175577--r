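# Classical statistics engine shared by all analysis stages.

#' Mixed factorial ANOVA with partial eta squared
#'
#' Fits a mixed factorial ANOVA with one two-level within-subjects factor and
#' one or two between-subjects factors, using Type-III sums of squares
#' (between-cell sizes in completer samples are typically unbalanced).
#' Between-subjects effects are tested against the between-subject error;
#' effects involving the within factor against the subject-by-within error.
#' Computation is delegated to [car::Anova()] on a multivariate linear model
#' with sum-to-zero contrasts; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' Participants missing either within-subject level are dropped (recorded in
#' the `dropped` attribute of the result).
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric outcome column.
#' @param subject Name of the participant identifier column.
#' @param within Name of the two-level within-subjects factor column.
#' @param between Character vector (length 1 or 2) of between-subjects factor
#'   columns, each with two levels.
#' @return Data frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `eta_p_sq`.
#' @examples
#' d <- expand.grid(id = 1:8, session = c("pre", "post"))
#' d$grp <- rep(rep(c("a", "b"), each = 4), 2)
#' set.seed(1); d$y <- rnorm(16)
#' mixed_anova(d, dv = "y", subject = "id", within = "session", between = "grp")
#' @export
mixed_anova <- function(data, dv, subject, within, between) {
  stopifnot(is.data.frame(data), length(between) %in% 1:2,
            all(c(dv, subject, within, between) %in% names(data)))
  data <- data[, c(subject, within, between, dv)]
  data[[within]] <- factor(data[[within]])
  w_levels <- levels(data[[within]])
  if (length(w_levels) != 2L) {
    stop("the within-subjects factor must have exactly two levels")
  }
  for (b in between) data[[b]] <- factor(data[[b]])

  # wide reshape; drop subjects lacking either within level
  split_by_id <- split(data, data[[subject]])
  keep <- vapply(split_by_id, function(d) {
    nrow(d) == 2L && setequal(d[[within]], w_levels) && !anyNA(d[[dv]])
  }, logical(1))
  dropped <- names(split_by_id)[!keep]
  wide_rows <- lapply(split_by_id[keep], function(d) {
    d <- d[match(w_levels, d[[within]]), ]
    out <- d[1L, between, drop = FALSE]
    out$.w1 <- d[[dv]][1L]
    out$.w2 <- d[[dv]][2L]
    out
  })
  wide <- do.call(rbind, wide_rows)
  cell <- interaction(wide[, between, drop = FALSE], drop = FALSE)
  if (any(table(cell) < 2L)) {
    stop("each between-subjects cell needs at least two participants")
  }

  rhs <- paste(between, collapse = " * ")
  contr <- stats::setNames(replicate(length(between), "contr.sum",
                                     simplify = FALSE), between)
  mod <- stats::lm(stats::as.formula(paste("cbind(.w1, .w2) ~", rhs)),
                   data = wide, contrasts = contr)
  idata <- data.frame(.session = factor(w_levels, levels = w_levels))
  av <- car::Anova(mod, idata = idata, idesign = ~.session, type = 3)
  # sphericity corrections are vacuous for a two-level within factor; car
  # warns when it cannot compute them for near-singular error SSP matrices
  tab <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
  tab <- tab[rownames(tab) != "(Intercept)", , drop = FALSE]

  eff <- gsub("\\.session", within, rownames(tab))
  res <- data.frame(
    effect = eff,
    F = unname(tab[, "F value"]),
    df1 = unname(tab[, "num Df"]),
    df2 = unname(tab[, "den Df"]),
    p = unname(tab[, "Pr(>F)"]),
    eta_p_sq = unname(tab[, "Sum Sq"] / (tab[, "Sum Sq"] + tab[, "Error SS"])),
    row.names = NULL
  )
  attr(res, "dropped") <- dropped
  attr(res, "n") <- nrow(wide)
  res
}

#' t-test with Hedges' g
#'
#' Student's pooled-variance t-test for independent samples (`df = n1 + n2 -
#' 2`) or a paired t-test, together with the bias-corrected standardized mean
#' difference (Hedges' g, correction factor `1 - 3 / (4 df - 1)`).
#'
#' @param x,y Numeric vectors.
#' @param paired Logical; paired test requires equal lengths.
#' @return List with `t`, `df`, `p`, `g`.
#' @export
t_test_g <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (stats::sd(d) == 0) stop("zero variance of paired differences")
    ht <- stats::t.test(x, y, paired = TRUE)
    df <- length(d) - 1L
    g_raw <- mean(d) / stats::sd(d)
  } else {
    n1 <- length(x); n2 <- length(y)
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
    if (sp2 == 0) stop("zero pooled variance")
    ht <- stats::t.test(x, y, var.equal = TRUE)
    g_raw <- (mean(x) - mean(y)) / sqrt(sp2)
  }
  J <- 1 - 3 / (4 * df - 1)
  list(t = unname(ht$statistic), df = df, p = ht$p.value, g = J * g_raw)
}

#' Mann-Whitney U test
#'
#' Rank-sum test reporting the U statistic for the first sample. The p-value
#' is exact (by enumeration) when `n1 * n2 <= 400` and there are no ties;
#' otherwise a normal approximation with tie and continuity corrections is
#' used.
#'
#' @param x,y Numeric vectors.
#' @return List with `U`, `p` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1, returned in the
#' input order), as used to correct the sequential session contrasts.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction, `df = (r - 1)(c - 1)`,
#' as used for the attrition-by-group comparison.
#'
#' @param counts Matrix (or table) of non-negative counts.
#' @return List with `chi2`, `df`, `p` and `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("table has a zero marginal")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' Extreme-outlier screen
#'
#' Flags values outside `[Q1 - 3 IQR, Q3 + 3 IQR]` (the box-and-whisker
#' extreme-outlier rule). Quartiles use linear interpolation between order
#' statistics (`stats::quantile()` type 7); fence membership can differ
#' under Tukey hinges, so the rule is fixed here.
#'
#' @param values Numeric vector, `n >= 4`.
#' @return List with `indices` (positions flagged) and `fences` (`lower`,
#'   `upper`).
#' @export
extreme_outliers <- function(values) {
  stopifnot(length(values) >= 4, all(is.finite(values)))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 3 * iqr, upper = q[2] + 3 * iqr)
  list(indices = which(values < fences[1] | values > fences[2]),
       fences = fences)
}

#' Sample size for a within-between interaction
#'
#' Smallest total N (rounded up to a multiple of the number of groups) at
#' which the group-by-measurement interaction test of a repeated-measures
#' design reaches the requested power. Effect size is converted as
#' `f2 = eta_p_sq / (1 - eta_p_sq)`; the noncentrality parameter is
#' `f2 * N * m / (1 - corr)` with `m` repeated measurements and correlation
#' `corr` among them, and the test has `df = (1, N - groups)`. Conventions
#' for repeated-measures noncentrality differ across software; the one used
#' here is stated exactly so results are reproducible.
#'
#' @param eta_p_sq Anticipated partial eta squared.
#' @param alpha Significance level.
#' @param power Requested power.
#' @param groups Number of between-subjects groups.
#' @param measurements Number of repeated measurements.
#' @param corr Assumed correlation among repeated measures.
#' @return Total sample size N (integer).
#' @export
rm_power_sample_size <- function(eta_p_sq, alpha = 0.05, power = 0.80,
                                 groups = 2, measurements = 2, corr = 0.5) {
  stopifnot(eta_p_sq > 0, eta_p_sq < 1, alpha > 0, alpha < 1,
            power > 0, power < 1, corr >= 0, corr < 1)
  f2 <- eta_p_sq / (1 - eta_p_sq)
  power_at <- function(N) {
    lambda <- f2 * N * measurements / (1 - corr)
    crit <- stats::qf(1 - alpha, 1, N - groups)
    1 - stats::pf(crit, 1, N - groups, ncp = lambda)
  }
  N <- 2 * groups
  while (power_at(N) < power) {
    N <- N + groups
    if (N > 1e6) stop("requested power unattainable")
  }
  as.integer(N)
}
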