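# Learning-curve analysis: sliding-window smoothing, one-knot linear spline
# fits with exhaustive knot search, group comparison of learning parameters,
# and sequential FDR-corrected session contrasts.

N_SESSIONS <- 16L
N_SMOOTHED <- 15L

#' Sliding-window smoothing of a training series
#'
#' Averages adjacent pairs of the 16 session outcomes (S1+S2, S2+S3, ...),
#' the smallest smoothing unit possible, yielding 15 data points that
#' attenuate session-to-session volatility before spline fitting.
#'
#' @param raw Numeric vector of exactly 16 finite session outcomes.
#' @return Numeric vector of 15 adjacent-pair means.
#' @examples
#' smooth_series(1:16)  # 1.5, 2.5, ..., 15.5
#' @export
smooth_series <- function(raw) {
  if (length(raw) != N_SESSIONS || !all(is.finite(raw))) {
    stop("`raw` must contain exactly 16 finite session outcomes")
  }
  (raw[-N_SESSIONS] + raw[-1L]) / 2
}

#' Fit a one-knot linear spline at a fixed knot
#'
#' Ordinary least squares of the 15 smoothed values on the basis
#' `{1, t, max(0, t - k)}` with `t = 1..15`: a continuous piecewise-linear
#' curve whose slope changes at data point `k`. `slope1` is the slope of the
#' first segment (the learning curve before asymptotic-like performance),
#' `slope2` the slope after the knot.
#'
#' @param values Numeric vector of 15 smoothed data points.
#' @param k Knot index, an integer in `[2, 14]`.
#' @return An object of class `spline_fit`: `knot_index`, `intercept`,
#'   `slope1`, `slope2`, `r_squared`, `degenerate`. A flat (zero-variance)
#'   series is degenerate: slopes are 0 and `r_squared` is `NA`.
#' @export
fit_spline_at_knot <- function(values, k) {
  if (length(values) != N_SMOOTHED || !all(is.finite(values))) {
    stop("`values` must contain exactly 15 finite data points")
  }
  k <- as.integer(k)
  if (k < 2L || k > 14L) stop("`k` must lie in [2, 14]")
  t <- seq_len(N_SMOOTHED)
  ss_tot <- sum((values - mean(values))^2)
  if (ss_tot < 1e-12) {
    return(structure(list(knot_index = k, intercept = values[1L],
                          slope1 = 0, slope2 = 0, r_squared = NA_real_,
                          degenerate = TRUE),
                     class = "spline_fit"))
  }
  hinge <- pmax(0, t - k)
  fit <- stats::lm(values ~ t + hinge)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  structure(list(knot_index = k,
                 intercept = unname(cf[1L]),
                 slope1 = unname(cf["t"]),
                 slope2 = unname(cf["t"] + cf["hinge"]),
                 r_squared = 1 - ss_res / ss_tot,
                 degenerate = FALSE),
            class = "spline_fit")
}

#' Select the best-fitting knot for one participant
#'
#' Fits the one-knot spline at every admissible knot (data points 2 through
#' 14, i.e., all points except the first and last) and returns the fit with
#' the highest R-squared. Ties — which arise, e.g., for perfectly linear
#' series — are broken toward the smallest knot (numerical ties within 1e-9
#' are treated as equal).
#'
#' @param values Numeric vector of 15 smoothed data points.
#' @return The winning `spline_fit`. For a flat series a degenerate fit with
#'   `knot_index = NA` is returned; such participants are excluded from
#'   group comparisons.
#' @export
select_best_knot <- function(values) {
  fits <- lapply(2:14, function(k) fit_spline_at_knot(values, k))
  if (fits[[1L]]$degenerate) {
    out <- fits[[1L]]
    out$knot_index <- NA_integer_
    return(out)
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  best <- which(r2 >= max(r2) - 1e-9)[1L]
  fits[[best]]
}

#' Compare learning parameters between two groups
#'
#' Compares the first-segment slope and the knot location between two groups
#' of participant spline fits with two-sided Mann-Whitney U tests, reporting
#' group mean, SD and median per measure alongside U, p and Hedges' g.
#' Degenerate (flat-series) fits are excluded.
#'
#' @param fits_a,fits_b Lists of `spline_fit` objects, one per participant.
#' @param labels Character vector of length 2 naming the groups.
#' @return Data frame with one row per measure (`first_slope`,
#'   `knot_location`).
#' @export
compare_learning_parameters <- function(fits_a, fits_b,
                                        labels = c("groupA", "groupB")) {
  take <- function(fits) {
    fits <- Filter(function(f) !f$degenerate, fits)
    data.frame(slope1 = vapply(fits, `[[`, numeric(1), "slope1"),
               knot = vapply(fits, function(f) as.numeric(f$knot_index),
                             numeric(1)))
  }
  a <- take(fits_a); b <- take(fits_b)
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each group needs at least two non-degenerate fits")
  }
  one <- function(xa, xb, measure) {
    mw <- mann_whitney_u(xa, xb)
    df <- length(xa) + length(xb) - 2L
    sp <- sqrt(((length(xa) - 1) * stats::var(xa) +
                  (length(xb) - 1) * stats::var(xb)) / df)
    g <- if (sp == 0) 0 else {
      (1 - 3 / (4 * df - 1)) * (mean(xa) - mean(xb)) / sp
    }
    data.frame(measure = measure,
               n_a = length(xa), mean_a = mean(xa), sd_a = stats::sd(xa),
               median_a = stats::median(xa),
               n_b = length(xb), mean_b = mean(xb), sd_b = stats::sd(xb),
               median_b = stats::median(xb),
               U = mw$U, p = mw$p, g = g)
  }
  out <- rbind(one(a$slope1, b$slope1, "first_slope"),
               one(a$knot, b$knot, "knot_location"))
  attr(out, "labels") <- labels
  out
}

#' Sequential session-contrast ANOVAs
#'
#' For each later session SN (N = 2..16) runs a 2 x 2 mixed ANOVA of the
#' session outcome with training schedule as the between-subjects factor and
#' session (S1 vs SN) as the within-subjects factor — 15 ANOVAs per task —
#' answering how many sessions are needed before performance departs from
#' S1. P-values for the group, session and interaction effects are corrected
#' with the Benjamini-Hochberg procedure; by default each effect's 15
#' p-values form one FDR family (`fdr_family = "per_effect"`), with a joint
#' 45-test family available as `"joint"`.
#'
#' Participants missing either session of a contrast are dropped from that
#' contrast only.
#'
#' @param sessions Long data frame of training outcomes for trained (WMT)
#'   participants with columns `id`, `group` (two levels), `session`
#'   (1..16) and `outcome`.
#' @param fdr_family `"per_effect"` or `"joint"`.
#' @return Data frame with 45 rows: `contrast` (e.g. `"S1_vs_S4"`),
#'   `effect` (`group`, `session`, `group:session`), `F`, `df1`, `df2`,
#'   `p_raw`, `p_fdr`.
#' @export
sequential_session_anovas <- function(sessions,
                                      fdr_family = c("per_effect", "joint")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(all(c("id", "group", "session", "outcome") %in% names(sessions)))
  rows <- list()
  for (N in 2:16) {
    d <- sessions[sessions$session %in% c(1L, N), ]
    d$session_f <- factor(ifelse(d$session == 1L, "S1", "SN"),
                          levels = c("S1", "SN"))
    res <- mixed_anova(d, dv = "outcome", subject = "id",
                       within = "session_f", between = "group")
    eff <- gsub("session_f", "session", res$effect)
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = sprintf("S1_vs_S%d", N), effect = eff,
      F = res$F, df1 = res$df1, df2 = res$df2, p_raw = res$p
    )
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  if (fdr_family == "per_effect") {
    for (e in unique(out$effect)) {
      sel <- out$effect == e
      out$p_fdr[sel] <- bh_fdr(out$p_raw[sel])
    }
  } else {
    out$p_fdr <- bh_fdr(out$p_raw)
  }
  rownames(out) <- NULL
  out
}
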