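# Simulate -> analyze -> report pipeline with config files, manifests and
# fixed CSV schemas.

#' Study configuration
#'
#' Bundles the cohort-generation parameters with the analysis switches. A
#' pipeline run is a pure function of (config, seed).
#'
#' @param cohort A [cohort_config()].
#' @param fdr_family FDR family for the sequential session contrasts:
#'   `"per_effect"` (each effect's 15 p-values form one family) or
#'   `"joint"` (one 45-test family).
#' @param outlier_sensitivity Logical: rerun the factorial ANOVAs excluding
#'   extreme outliers where any are flagged.
#' @param seed Integer seed; overrides `cohort$seed` when given.
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_config(),
                         fdr_family = c("per_effect", "joint"),
                         outlier_sensitivity = TRUE,
                         seed = NULL) {
  fdr_family <- match.arg(fdr_family)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, fdr_family = fdr_family,
                 outlier_sensitivity = outlier_sensitivity,
                 seed = cohort$seed),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [study_config()] and [cohort_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top level may
#'   contain `cohort` (a mapping of [cohort_config()] arguments),
#'   `fdr_family`, `outlier_sensitivity` and `seed`.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known_top <- c("cohort", "fdr_family", "outlier_sensitivity", "seed")
  bad <- setdiff(names(raw), known_top)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  cohort_args <- raw$cohort %||% list()
  known_cohort <- names(formals(cohort_config))
  bad <- setdiff(names(cohort_args), known_cohort)
  if (length(bad)) {
    stop("unknown cohort config keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(cohort_args$attrition_prob)) {
    cohort_args$attrition_prob <- unlist(cohort_args$attrition_prob)
  }
  cohort <- do.call(cohort_config, cohort_args)
  study_config(cohort = cohort,
               fdr_family = raw$fdr_family %||% "per_effect",
               outlier_sensitivity = raw$outlier_sensitivity %||% TRUE,
               seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass_deep(config),
                                           auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else {
    if (inherits(x, "Date")) format(x, "%Y-%m-%d") else unclass(x)
  }
}

#' Simulate a study and write its data files
#'
#' Generates a cohort from the configuration, writes `participants.csv` and
#' `sessions.csv` plus a `manifest.json` recording the config hash, seed,
#' package version, per-table row counts and the exclusion log (dropouts
#' and the session they stopped after).
#'
#' @param config A `study_config`.
#' @param out_dir Output directory.
#' @return The simulated `wmt_cohort`, invisibly.
#' @export
simulate_study <- function(config = study_config(), out_dir) {
  stopifnot(inherits(config, "study_config"))
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, out_dir)
  p <- cohort$participants
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("wmtsim")),
    n_participants = nrow(p),
    n_session_rows = nrow(cohort$sessions),
    n_completed = sum(p$completed),
    exclusion_log = if (any(!p$completed)) {
      data.frame(id = p$id[!p$completed],
                 reason = sprintf("dropped out after session %d",
                                  p$last_session[!p$completed]))
    } else {
      data.frame(id = character(), reason = character())
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cohort)
}

# long pre/post table for one training task (S1 vs S16 outcomes)
training_prepost <- function(cohort, task) {
  s <- cohort$sessions
  p <- cohort$participants
  s <- s[s$task == task & s$session %in% c(1L, 16L), ]
  d <- merge(s, p[, c("id", "treatment", "schedule", "completed")], by = "id")
  d <- d[d$completed, ]
  d$session_f <- factor(ifelse(d$session == 1L, "first", "final"),
                        levels = c("first", "final"))
  d[, c("id", "treatment", "schedule", "session_f", "mean_nback")]
}

# long pre/post table for one transfer measure ("dsf", "dsb", "rr")
transfer_prepost <- function(cohort, measure) {
  p <- cohort$participants
  p <- p[p$completed, ]
  pre <- p[[paste0(measure, "_pre")]]
  post <- p[[paste0(measure, "_post")]]
  data.frame(
    id = rep(p$id, 2L), treatment = rep(p$treatment, 2L),
    schedule = rep(p$schedule, 2L),
    session_f = factor(rep(c("pre", "post"), each = nrow(p)),
                       levels = c("pre", "post")),
    score = c(pre, post)
  )
}

# 2x2 between-subjects ANOVA (Type III, sum contrasts)
between_anova_2x2 <- function(data, dv, factors) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  contr <- stats::setNames(replicate(length(factors), "contr.sum",
                                     simplify = FALSE), factors)
  mod <- stats::lm(stats::as.formula(
    paste(dv, "~", paste(factors, collapse = " * "))),
    data = data, contrasts = contr)
  tab <- car::Anova(mod, type = 3)
  res <- as.data.frame(tab)
  res <- res[!rownames(res) %in% c("(Intercept)", "Residuals"), , drop = FALSE]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_err <- tab["Residuals", "Df"]
  data.frame(effect = rownames(res), F = res$`F value`, df1 = res$Df,
             df2 = df_err, p = res$`Pr(>F)`,
             eta_p_sq = res$`Sum Sq` / (res$`Sum Sq` + ss_err),
             row.names = NULL)
}

#' Attrition rate
#'
#' `(number that did not complete / number assigned) * 100`.
#'
#' @param n_assigned,n_completed Counts.
#' @return Percentage.
#' @export
attrition_rate <- function(n_assigned, n_completed) {
  stopifnot(n_completed <= n_assigned, n_assigned > 0)
  (n_assigned - n_completed) / n_assigned * 100
}

run_measure_anova <- function(long, dv) {
  mixed_anova(long, dv = dv, subject = "id", within = "session_f",
              between = c("treatment", "schedule"))
}

prepost_wide <- function(long, dv) {
  lv <- levels(long$session_f)
  d1 <- long[long$session_f == lv[1L], ]
  d2 <- long[long$session_f == lv[2L], ]
  d1 <- d1[d1$id %in% d2$id, ]
  m <- match(d1$id, d2$id)
  data.frame(id = d1$id, treatment = d1$treatment, schedule = d1$schedule,
             y1 = d1[[dv]], y2 = d2[[dv]][m])
}

followup_ts <- function(long, dv) {
  wide <- prepost_wide(long, dv)
  y1 <- wide$y1
  y2 <- wide$y2
  wmt <- wide$treatment == "wmt"
  as_row <- function(label, tt) {
    data.frame(comparison = label, t = tt$t, df = tt$df, p = tt$p, g = tt$g)
  }
  rbind(
    as_row("wmt_vs_control_final", t_test_g(y2[wmt], y2[!wmt])),
    as_row("wmt_vs_control_first", t_test_g(y1[wmt], y1[!wmt])),
    as_row("wmt_final_vs_first", t_test_g(y2[wmt], y1[wmt], paired = TRUE)),
    as_row("control_final_vs_first",
           t_test_g(y2[!wmt], y1[!wmt], paired = TRUE))
  )
}

spline_fits_by_schedule <- function(cohort, task) {
  p <- cohort$participants
  ids <- p$id[p$completed & p$treatment == "wmt"]
  s <- cohort$sessions
  fits <- list(distributed = list(), intensive = list())
  excluded <- character(0)
  for (pid in ids) {
    raw <- s$mean_nback[s$id == pid & s$task == task][order(
      s$session[s$id == pid & s$task == task])]
    fit <- select_best_knot(smooth_series(raw))
    sched <- p$schedule[p$id == pid]
    if (fit$degenerate) {
      excluded <- c(excluded, pid)
    } else {
      fits[[sched]] <- c(fits[[sched]], list(fit))
    }
  }
  list(fits = fits, excluded = excluded)
}

#' Analyze a study
#'
#' Runs the full analysis battery on a cohort (or a directory written by
#' [simulate_study()]/[write_cohort()]): baseline comparability tests, the
#' factorial training and transfer ANOVAs with interaction-gated follow-up
#' t-tests, the sequential FDR-corrected session contrasts, the spline
#' learning-curve comparison, the attrition and questionnaire summaries, and
#' sensitivity reruns excluding extreme outliers. Only completers enter the
#' pre/post analyses; the `exclusions` element accounts for every enrollee.
#'
#' @param cohort A `wmt_cohort` or a directory path.
#' @param config A `study_config` (analysis switches only; the cohort
#'   parameters are not re-used).
#' @return An object of class `wmt_results`.
#' @export
analyze_study <- function(cohort, config = study_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "wmt_cohort"))
  p <- cohort$participants
  s <- cohort$sessions
  if (nrow(p) == 0L) stop("empty cohort")

  # -- baseline comparability -------------------------------------------
  s1 <- s[s$session == 1L, ]
  baseline_vars <- list(
    age = p$age,
    dsf_pre = p$dsf_pre, dsb_pre = p$dsb_pre, rr_pre = p$rr_pre,
    verbal_s1 = s1$mean_nback[s1$task == "verbal"][match(p$id,
      s1$id[s1$task == "verbal"])],
    spatial_s1 = s1$mean_nback[s1$task == "spatial"][match(p$id,
      s1$id[s1$task == "spatial"])]
  )
  baseline <- do.call(rbind, lapply(names(baseline_vars), function(v) {
    y <- baseline_vars[[v]]
    ok <- !is.na(y)
    fit <- stats::anova(stats::lm(y[ok] ~ factor(p$group[ok])))
    data.frame(variable = v, test = "one_way_anova",
               statistic = fit$`F value`[1], df1 = fit$Df[1],
               df2 = fit$Df[2], p = fit$`Pr(>F)`[1])
  }))
  sex_tab <- table(p$sex, p$group)
  sex_chi <- chi_square_independence(sex_tab)
  baseline <- rbind(baseline,
                    data.frame(variable = "sex", test = "chi_square",
                               statistic = sex_chi$chi2, df1 = sex_chi$df,
                               df2 = NA, p = sex_chi$p))

  # -- factorial ANOVAs (training + transfer) ---------------------------
  measures <- list(
    verbal_nback = list(long = training_prepost(cohort, "verbal"),
                        dv = "mean_nback"),
    spatial_nback = list(long = training_prepost(cohort, "spatial"),
                         dv = "mean_nback"),
    dsf = list(long = transfer_prepost(cohort, "dsf"), dv = "score"),
    dsb = list(long = transfer_prepost(cohort, "dsb"), dv = "score"),
    rr = list(long = transfer_prepost(cohort, "rr"), dv = "score")
  )
  anovas <- list()
  followups <- list()
  sensitivity <- list()
  for (m in names(measures)) {
    long <- measures[[m]]$long
    dv <- measures[[m]]$dv
    res <- run_measure_anova(long, dv)
    res$effect <- gsub("session_f", "session", res$effect)
    anovas[[m]] <- res
    inter_p <- res$p[res$effect == "treatment:session"]
    if (length(inter_p) == 1L && !is.na(inter_p) && inter_p < 0.05) {
      followups[[m]] <- followup_ts(long, dv)
    }
    if (isTRUE(config$outlier_sensitivity)) {
      wide <- prepost_wide(long, dv)
      ok <- stats::complete.cases(wide$y1, wide$y2)
      wide <- wide[ok, ]
      out <- extreme_outliers(wide$y2 - wide$y1)
      if (length(out$indices) > 0L) {
        drop_ids <- wide$id[out$indices]
        res2 <- run_measure_anova(long[!long$id %in% drop_ids, ], dv)
        res2$effect <- gsub("session_f", "session", res2$effect)
        sensitivity[[m]] <- list(excluded_ids = drop_ids, anova = res2)
      }
    }
  }

  # -- sequential session contrasts (WMT only) --------------------------
  wmt_ids <- p$id[p$treatment == "wmt" & p$completed]
  step1 <- list()
  for (task in c("verbal", "spatial")) {
    d <- s[s$id %in% wmt_ids & s$task == task, ]
    d <- merge(d, p[, c("id", "schedule")], by = "id")
    names(d)[names(d) == "schedule"] <- "group"
    names(d)[names(d) == "mean_nback"] <- "outcome"
    step1[[task]] <- sequential_session_anovas(d, fdr_family =
                                                 config$fdr_family)
  }

  # -- spline learning-curve comparison ---------------------------------
  table3 <- list()
  for (task in c("verbal", "spatial")) {
    sf <- spline_fits_by_schedule(cohort, task)
    table3[[task]] <- list(
      comparison = compare_learning_parameters(
        sf$fits$distributed, sf$fits$intensive,
        labels = c("distributed_wmt", "intensive_wmt")),
      excluded = sf$excluded
    )
  }

  # -- attrition + questionnaire ----------------------------------------
  assigned <- table(factor(p$group, levels = GROUP_LEVELS))
  completed <- table(factor(p$group[p$completed], levels = GROUP_LEVELS))
  attr_tab <- rbind(completed = as.integer(completed),
                    dropped = as.integer(assigned - completed))
  colnames(attr_tab) <- GROUP_LEVELS
  attr_chi <- tryCatch(chi_square_independence(attr_tab),
                       error = function(e) NULL)
  attrition <- list(
    by_group = data.frame(group = GROUP_LEVELS,
                          assigned = as.integer(assigned),
                          completed = as.integer(completed),
                          rate_pct = attrition_rate(as.integer(assigned),
                                                    as.integer(completed))),
    overall_rate_pct = attrition_rate(nrow(p), sum(p$completed)),
    chi_square = attr_chi
  )

  q <- p[p$completed, ]
  questionnaire <- list(
    n_completers = nrow(q),
    n_questionnaire = sum(q$questionnaire),
    completion_pct = if (nrow(q)) sum(q$questionnaire) / nrow(q) * 100 else NA,
    agree_pct = vapply(c("likert_challenging", "likert_engaging",
                         "likert_adopt"), function(v) {
      x <- q[[v]][!is.na(q[[v]])]
      if (length(x)) mean(x >= 4) * 100 else NA_real_
    }, numeric(1))
  )
  likert <- list()
  for (v in c("likert_challenging", "likert_engaging", "likert_adopt",
              "likert_schedule")) {
    d <- q[!is.na(q[[v]]), c("treatment", "schedule", v)]
    likert[[v]] <- between_anova_2x2(d, v, c("treatment", "schedule"))
  }

  exclusions <- data.frame(
    id = p$id,
    status = ifelse(p$completed, "analyzed", "excluded"),
    reason = ifelse(p$completed, "",
                    sprintf("dropped out after session %d", p$last_session))
  )

  structure(list(baseline = baseline, anovas = anovas,
                 followups = followups, step1 = step1, table3 = table3,
                 attrition = attrition, questionnaire = questionnaire,
                 likert = likert, sensitivity = sensitivity,
                 exclusions = exclusions,
                 n = list(enrolled = nrow(p), completed = sum(p$completed))),
            class = "wmt_results")
}

#' Write analysis results as CSV files
#'
#' Emits the fixed-schema result files: `baseline.csv`, `table2.csv`
#' (stacked factorial ANOVAs), `followups.csv`, `step1_verbal.csv`,
#' `step1_spatial.csv`, `table3.csv`, `attrition.csv`, `likert.csv` and
#' `exclusions.csv`.
#'
#' @param results A `wmt_results`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "wmt_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(results$baseline, "baseline.csv")
  t2 <- do.call(rbind, lapply(names(results$anovas), function(m) {
    cbind(measure = m, results$anovas[[m]])
  }))
  w(t2, "table2.csv")
  if (length(results$followups)) {
    fu <- do.call(rbind, lapply(names(results$followups), function(m) {
      cbind(measure = m, results$followups[[m]])
    }))
    w(fu, "followups.csv")
  }
  w(results$step1$verbal, "step1_verbal.csv")
  w(results$step1$spatial, "step1_spatial.csv")
  t3 <- do.call(rbind, lapply(names(results$table3), function(task) {
    cbind(task = task, results$table3[[task]]$comparison)
  }))
  w(t3, "table3.csv")
  w(results$attrition$by_group, "attrition.csv")
  lik <- do.call(rbind, lapply(names(results$likert), function(v) {
    cbind(question = v, results$likert[[v]])
  }))
  w(lik, "likert.csv")
  w(results$exclusions, "exclusions.csv")
  invisible(dir)
}

fmt_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

#' Render a markdown report
#'
#' Produces a deterministic, human-readable markdown report of a results
#' bundle: the factorial ANOVA and spline-comparison tables, the sequential
#' contrast summary, the attrition paragraph, questionnaire summaries and a
#' consistency-check section covering exclusion arithmetic.
#'
#' @param results A `wmt_results`.
#' @return Character vector of markdown lines.
#' @export
report_study <- function(results) {
  stopifnot(inherits(results, "wmt_results"))
  out <- c("# Synthetic working-memory-training study report", "")

  out <- c(out, "## Factorial ANOVAs (training and transfer)", "",
           "| Measure | Effect | F | p | partial eta^2 |",
           "|---|---|---|---|---|")
  for (m in names(results$anovas)) {
    a <- results$anovas[[m]]
    out <- c(out, sprintf("| %s | %s | %.2f | %s | %.2f |",
                          m, a$effect, a$F, fmt_p(a$p), a$eta_p_sq))
  }

  out <- c(out, "", "## Sequential session contrasts (FDR-corrected)", "")
  for (task in names(results$step1)) {
    st <- results$step1[[task]]
    sig <- st[st$effect == "session" & st$p_fdr < 0.05, "contrast"]
    out <- c(out, sprintf(
      "- %s: session effect significant (FDR < .05) for %s", task,
      if (length(sig)) paste(sig, collapse = ", ") else "no contrast"))
  }

  out <- c(out, "", "## Learning-curve parameters (WMT groups)", "",
           paste("| Task | Measure | Distributed M ± SD (Mdn) |",
                 "Intensive M ± SD (Mdn) | U | p | g |"),
           "|---|---|---|---|---|---|---|")
  for (task in names(results$table3)) {
    cmp <- results$table3[[task]]$comparison
    out <- c(out, sprintf(
      "| %s | %s | %.2f ± %.2f (%.2f) | %.2f ± %.2f (%.2f) | %.2f | %s | %.2f |",
      task, cmp$measure, cmp$mean_a, cmp$sd_a, cmp$median_a,
      cmp$mean_b, cmp$sd_b, cmp$median_b, cmp$U, fmt_p(cmp$p), cmp$g))
  }

  att <- results$attrition
  out <- c(out, "", "## Attrition and acceptability", "",
           sprintf(paste0("The overall attrition rate was %.2f%% (started:",
                          " n = %d; completed: n = %d)."),
                   att$overall_rate_pct, results$n$enrolled,
                   results$n$completed))
  if (!is.null(att$chi_square)) {
    out <- c(out, sprintf(
      "Attrition did not differ / differed by group: chi2(%d) = %.2f, p = %s.",
      att$chi_square$df, att$chi_square$chi2, fmt_p(att$chi_square$p)))
  }
  out <- c(out, sprintf("Per-group rates: %s.",
                        paste(sprintf("%s %.2f%%", att$by_group$group,
                                      att$by_group$rate_pct),
                              collapse = "; ")))
  qn <- results$questionnaire
  out <- c(out, sprintf(
    "Questionnaire completion: %d of %d completers (%.0f%%).",
    qn$n_questionnaire, qn$n_completers, qn$completion_pct))

  out <- c(out, "", "## Consistency checks", "",
           sprintf("- enrolled %d = analyzed %d + excluded %d",
                   results$n$enrolled,
                   sum(results$exclusions$status == "analyzed"),
                   sum(results$exclusions$status == "excluded")))
  if (length(results$sensitivity)) {
    for (m in names(results$sensitivity)) {
      out <- c(out, sprintf(
        "- sensitivity rerun for %s excluded: %s", m,
        paste(results$sensitivity[[m]]$excluded_ids, collapse = ", ")))
    }
  }
  out
}
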