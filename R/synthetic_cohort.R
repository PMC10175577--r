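# Synthetic study generator: group allocation, schedule calendars,
# per-session training outcomes, transfer scores, questionnaire, attrition.

GROUP_LEVELS <- c("distributed_wmt", "intensive_wmt",
                  "distributed_control", "intensive_control")

group_label <- function(schedule, treatment) {
  paste(schedule, ifelse(treatment == "wmt", "wmt", "control"), sep = "_")
}

#' Individual learner parameters
#'
#' Latent parameters of one simulated learner. Working memory capacity on
#' session t is piecewise linear with a plateau:
#' `capacity(t) = baseline + slope1 * min(t, knot_session) + slope2 * max(0,
#' t - knot_session)`, so training gain accrues at `slope1` capacity units
#' per session until `knot_session` and at `slope2` (approximately zero)
#' afterwards. `discrim` and `lapse` parameterize the logistic response
#' policy ([responder_logistic()]) that turns capacity into block responses.
#'
#' @param baseline Starting capacity in load-level units (>= 1).
#' @param slope1 Capacity gain per session before the plateau.
#' @param slope2 Capacity gain per session after the plateau.
#' @param knot_session Session at which the plateau begins (2-14).
#' @param discrim Logistic slope per load-level unit.
#' @param lapse Lapse rate in `[0, 0.2]`.
#' @return An object of class `learner_params` (includes the derived total
#'   `gain = slope1 * knot_session`).
#' @export
learner_params <- function(baseline = 2, slope1 = 0.15, slope2 = 0,
                           knot_session = 8L, discrim = 3, lapse = 0.05) {
  stopifnot(baseline >= 1, slope1 >= slope2, lapse >= 0, lapse <= 0.2,
            knot_session >= 2, knot_session <= 14)
  structure(list(baseline = baseline, slope1 = slope1, slope2 = slope2,
                 knot_session = as.integer(knot_session),
                 gain = slope1 * knot_session,
                 discrim = discrim, lapse = lapse),
            class = "learner_params")
}

#' Latent capacity at a given session
#'
#' Evaluates the piecewise-linear-with-plateau learning curve of a learner.
#'
#' @param params A [learner_params()].
#' @param session Session index (vectorized).
#' @return Numeric capacity in load-level units.
#' @export
capacity_at <- function(params, session) {
  params$baseline + params$slope1 * pmin(session, params$knot_session) +
    params$slope2 * pmax(0, session - params$knot_session)
}

#' Cohort configuration
#'
#' Study-level parameters of the synthetic cohort. Defaults mirror the
#' reference trial design: four groups (distributed/intensive crossed with
#' WMT/active control) of 20 enrollees each (yielding around 17-18
#' completers per group under the default attrition), 16 training sessions,
#' group-specific attrition probabilities matching the observed per-group
#' rates, no programmed transfer or pre-to-post effect (trained capacity
#' gains are programmed through the learner parameters instead), and a
#' Tuesday start date so calendars follow the canonical Tue/Thu and Tue-Fri
#' examples.
#'
#' @param n_per_group Participants enrolled per group.
#' @param attrition_prob Dropout probability; a single value or a named
#'   vector over the four groups.
#' @param treatment_transfer_effect Standardized effect added to WMT
#'   participants' post-training transfer scores.
#' @param session_effect Standardized pre-to-post change common to all
#'   groups (e.g., practice effects on the reasoning task).
#' @param seed Integer seed for the whole cohort; `NULL` leaves the RNG
#'   state untouched.
#' @param start_date First session date (a `Date` or ISO-8601 string).
#' @param training_model `"staircase"` plays every block of every session
#'   through the task engine; `"latent"` draws session outcomes directly
#'   from the latent learning curve with matched noise and granularity (for
#'   large simulation studies that only consume session outcomes).
#' @param learner Named list of population parameters for the latent
#'   learner distribution (means/SDs of baseline and slope, knot range,
#'   discrimination, lapse).
#' @param transfer Named list of population parameters for transfer-task
#'   latents (digit-span forward/backward means and SDs, reasoning ability
#'   mean and SD, span responder discrimination).
#' @param questionnaire_prob Probability that a completer fills in the
#'   end-of-training questionnaire.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 20L,
                          attrition_prob = c(distributed_wmt = 0.15,
                                             intensive_wmt = 0.143,
                                             distributed_control = 0,
                                             intensive_control = 0.10),
                          treatment_transfer_effect = 0,
                          session_effect = 0,
                          seed = NULL,
                          start_date = as.Date("2021-02-02"),
                          training_model = c("staircase", "latent"),
                          learner = list(),
                          transfer = list(),
                          questionnaire_prob = 0.93) {
  training_model <- match.arg(training_model)
  if (length(attrition_prob) == 1L) {
    attrition_prob <- stats::setNames(rep(attrition_prob, 4), GROUP_LEVELS)
  }
  stopifnot(setequal(names(attrition_prob), GROUP_LEVELS),
            all(attrition_prob >= 0 & attrition_prob <= 1),
            n_per_group >= 1)
  learner_defaults <- list(baseline_mean = 2, baseline_sd = 0.5,
                           slope1_mean = 0.15, slope1_sd = 0.05,
                           slope2 = 0, knot_min = 5L, knot_max = 11L,
                           discrim = 3, lapse = 0.05)
  transfer_defaults <- list(dsf_mean = 6.3, dsf_sd = 1.1,
                            dsb_mean = 4.8, dsb_sd = 1.1,
                            rr_mean = 2.5, rr_sd = 1.2,
                            span_discrim = 2.5)
  learner <- utils::modifyList(learner_defaults, learner)
  transfer <- utils::modifyList(transfer_defaults, transfer)
  structure(list(n_per_group = as.integer(n_per_group),
                 attrition_prob = attrition_prob[GROUP_LEVELS],
                 treatment_transfer_effect = treatment_transfer_effect,
                 session_effect = session_effect,
                 seed = seed,
                 start_date = as.Date(start_date),
                 training_model = training_model,
                 learner = learner,
                 transfer = transfer,
                 questionnaire_prob = questionnaire_prob),
            class = "cohort_config")
}

#' Allocate participants to groups
#'
#' Reproduces the trial's allocation scheme: training schedule alternates
#' with enrolment order (distributed, intensive, distributed, ...); within
#' each schedule, treatment (WMT vs active control) is assigned 1:1 by
#' blocked randomization in pairs; and the task performed first in session
#' one is counterbalanced within each of the four resulting groups, again in
#' randomized pairs, so that for even group sizes exactly half of every
#' group starts with the verbal task.
#'
#' @param n_total Total number of enrollees (>= 4).
#' @return Data frame with columns `id`, `schedule`, `treatment`,
#'   `task_order` (`"verbal_first"`/`"spatial_first"`) and `group`.
#' @export
allocate_groups <- function(n_total) {
  stopifnot(n_total >= 4)
  blocked_pairs <- function(n, values) {
    out <- character(n)
    i <- 1L
    while (i <= n) {
      pair <- sample(values)
      out[i] <- pair[1L]
      if (i + 1L <= n) out[i + 1L] <- pair[2L]
      i <- i + 2L
    }
    out
  }
  schedule <- rep(c("distributed", "intensive"), length.out = n_total)
  treatment <- character(n_total)
  for (s in c("distributed", "intensive")) {
    idx <- which(schedule == s)
    treatment[idx] <- blocked_pairs(length(idx), c("wmt", "control"))
  }
  task_order <- character(n_total)
  for (g in unique(group_label(schedule, treatment))) {
    idx <- which(group_label(schedule, treatment) == g)
    task_order[idx] <- blocked_pairs(length(idx),
                                     c("verbal_first", "spatial_first"))
  }
  data.frame(id = sprintf("P%03d", seq_len(n_total)),
             schedule = schedule, treatment = treatment,
             task_order = task_order,
             group = group_label(schedule, treatment))
}

#' Build a 16-session training calendar
#'
#' Distributed schedule: two sessions per week for eight weeks, with two
#' days between the week's sessions and a five-day gap before the next week
#' (e.g., Tue/Thu every week). Intensive schedule: four sessions per week on
#' consecutive days for four weeks, with a four-day gap before the next week
#' (e.g., Tue-Fri).
#'
#' @param schedule `"distributed"` or `"intensive"`.
#' @param start_date First session date.
#' @return Vector of 16 `Date`s.
#' @export
build_calendar <- function(schedule = c("distributed", "intensive"),
                           start_date = as.Date("2021-02-02")) {
  schedule <- match.arg(schedule)
  offsets <- schedule_offsets(schedule)
  as.Date(start_date) + offsets
}

schedule_offsets <- function(schedule) {
  if (schedule == "distributed") {
    rep(0:7 * 7L, each = 2L) + c(0L, 2L)
  } else {
    rep(0:3 * 7L, each = 4L) + 0:3
  }
}

#' Validate a session calendar against its schedule
#'
#' Checks that 16 ascending dates reproduce the offset pattern of
#' [build_calendar()] anchored at the first date. Fewer than 16 dates is an
#' incomplete-participant signal, not an error.
#'
#' @param dates Vector of session `Date`s, ascending.
#' @param schedule `"distributed"` or `"intensive"`.
#' @return List with `valid`, `incomplete` and a character vector
#'   `violations` naming the offending weeks.
#' @export
validate_schedule <- function(dates, schedule = c("distributed", "intensive")) {
  schedule <- match.arg(schedule)
  dates <- as.Date(dates)
  if (length(dates) < 16L) {
    return(list(valid = FALSE, incomplete = TRUE,
                violations = sprintf("only %d of 16 sessions present",
                                     length(dates))))
  }
  if (length(dates) > 16L) {
    return(list(valid = FALSE, incomplete = FALSE,
                violations = "more than 16 session dates"))
  }
  expected <- schedule_offsets(schedule)
  observed <- as.integer(dates - dates[1L])
  per_week <- if (schedule == "distributed") 2L else 4L
  bad <- which(observed != expected)
  violations <- vapply(bad, function(i) {
    sprintf("week %d: session %d at day offset %d, expected %d",
            (i - 1L) %/% per_week + 1L, i, observed[i], expected[i])
  }, character(1))
  list(valid = length(bad) == 0L, incomplete = FALSE,
       violations = violations)
}

draw_learner <- function(config, trained) {
  lp <- config$learner
  baseline <- max(1, stats::rnorm(1, lp$baseline_mean, lp$baseline_sd))
  if (trained) {
    slope1 <- max(0, stats::rnorm(1, lp$slope1_mean, lp$slope1_sd))
    knot <- sample(lp$knot_min:lp$knot_max, 1L)
    learner_params(baseline = baseline, slope1 = slope1, slope2 = lp$slope2,
                   knot_session = knot, discrim = lp$discrim,
                   lapse = lp$lapse)
  } else {
    learner_params(baseline = baseline, slope1 = 0, slope2 = 0,
                   knot_session = 8L, discrim = lp$discrim, lapse = lp$lapse)
  }
}

simulate_outcome_series <- function(params, n_sessions, config, task_cfg) {
  caps <- capacity_at(params, seq_len(n_sessions))
  if (config$training_model == "staircase") {
    vapply(caps, function(cap) {
      run_session(responder_logistic(cap, params$discrim, params$lapse),
                  task_cfg)$outcome
    }, numeric(1))
  } else {
    # latent shortcut: staircase hovers about half a level below capacity;
    # noise SD 0.15 matches the engine's measured stationary outcome SD and
    # granularity 0.2 matches the mean of five integer levels
    raw <- caps - 0.5 + stats::rnorm(n_sessions, 0, 0.15)
    pmax(1, round(raw * 5) / 5)
  }
}

#' Simulate one participant
#'
#' Produces the complete record of one enrollee: a schedule-valid session
#' calendar, per-session verbal and spatial training outcomes driven by the
#' latent learning curve (active controls have a flat curve), pre/post
#' transfer scores discretized through the task simulators, questionnaire
#' responses, and attrition (dropout is completely at random before a
#' uniformly drawn session).
#'
#' @param alloc One-row data frame as returned by [allocate_groups()].
#' @param config A [cohort_config()].
#' @param params Optional named list with `verbal` and `spatial`
#'   [learner_params()]; drawn from the population model when omitted.
#' @return List with `participant` (one-row data frame) and `sessions`
#'   (long data frame of performed sessions).
#' @export
simulate_participant <- function(alloc, config = cohort_config(),
                                 params = NULL) {
  trained <- alloc$treatment == "wmt"
  if (is.null(params)) {
    params <- list(verbal = draw_learner(config, trained),
                   spatial = draw_learner(config, trained))
  }
  grp <- group_label(alloc$schedule, alloc$treatment)
  dropout <- stats::runif(1) < config$attrition_prob[[grp]]
  last_session <- if (dropout) sample(1:15, 1L) else 16L
  completed <- last_session == 16L

  dates <- build_calendar(alloc$schedule, config$start_date)
  cfg_v <- nback_config("verbal")
  cfg_s <- nback_config("spatial")
  verbal <- simulate_outcome_series(params$verbal, last_session, config, cfg_v)
  spatial <- simulate_outcome_series(params$spatial, last_session, config,
                                     cfg_s)
  sessions <- data.frame(
    id = alloc$id,
    task = rep(c("verbal", "spatial"), each = last_session),
    session = rep(seq_len(last_session), 2L),
    date = format(dates[rep(seq_len(last_session), 2L)], "%Y-%m-%d"),
    mean_nback = c(verbal, spatial)
  )

  tr <- config$transfer
  shift <- config$session_effect +
    if (trained) config$treatment_transfer_effect else 0
  span_obs <- function(latent, direction) {
    simulate_digit_span(latent, span_protocol(direction),
                        discrim = tr$span_discrim)$span
  }
  dsf_lat <- stats::rnorm(1, tr$dsf_mean, tr$dsf_sd)
  dsb_lat <- stats::rnorm(1, tr$dsb_mean, tr$dsb_sd)
  rr_lat <- stats::rnorm(1, tr$rr_mean, tr$rr_sd)
  dsf_pre <- span_obs(dsf_lat, "forward")
  dsb_pre <- span_obs(dsb_lat, "backward")
  rr_pre <- simulate_reasoning(rr_lat)$score
  if (completed) {
    dsf_post <- span_obs(dsf_lat + shift * tr$dsf_sd, "forward")
    dsb_post <- span_obs(dsb_lat + shift * tr$dsb_sd, "backward")
    rr_post <- simulate_reasoning(rr_lat + shift * tr$rr_sd)$score
  } else {
    dsf_post <- dsb_post <- rr_post <- NA_integer_
  }

  questionnaire <- completed && stats::runif(1) < config$questionnaire_prob
  likert <- if (questionnaire) {
    c(challenging = sample(1:5, 1, prob = c(0.01, 0.02, 0.05, 0.42, 0.50)),
      engaging = sample(1:5, 1, prob = c(0.02, 0.06, 0.16, 0.46, 0.30)),
      adopt = sample(1:5, 1, prob = c(0.05, 0.10, 0.20, 0.40, 0.25)),
      schedule_opt = sample(1:5, 1, prob = c(0.03, 0.07, 0.30, 0.40, 0.20)))
  } else {
    c(challenging = NA_integer_, engaging = NA_integer_,
      adopt = NA_integer_, schedule_opt = NA_integer_)
  }

  age <- round(min(85, max(55, stats::rnorm(1, 65.9, 6.8))), 1)
  participant <- data.frame(
    id = alloc$id, schedule = alloc$schedule, treatment = alloc$treatment,
    group = grp, task_order = alloc$task_order,
    age = age, sex = sample(c("female", "male"), 1, prob = c(0.73, 0.27)),
    completed = completed, last_session = last_session,
    dsf_pre = as.integer(dsf_pre), dsf_post = as.integer(dsf_post),
    dsb_pre = as.integer(dsb_pre), dsb_post = as.integer(dsb_post),
    rr_pre = as.integer(rr_pre), rr_post = as.integer(rr_post),
    questionnaire = questionnaire,
    likert_challenging = as.integer(likert[["challenging"]]),
    likert_engaging = as.integer(likert[["engaging"]]),
    likert_adopt = as.integer(likert[["adopt"]]),
    likert_schedule = as.integer(likert[["schedule_opt"]])
  )
  list(participant = participant, sessions = sessions)
}

#' Simulate a full study cohort
#'
#' Allocates `4 * n_per_group` enrollees, simulates every participant and
#' assembles the tidy study tables.
#'
#' @param config A [cohort_config()].
#' @return An object of class `wmt_cohort`: a list with `participants` (one
#'   row per enrollee), `sessions` (long per-task, per-session outcomes) and
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  alloc <- allocate_groups(4L * config$n_per_group)
  sims <- lapply(seq_len(nrow(alloc)),
                 function(i) simulate_participant(alloc[i, ], config))
  participants <- do.call(rbind, lapply(sims, `[[`, "participant"))
  sessions <- do.call(rbind, lapply(sims, `[[`, "sessions"))
  rownames(participants) <- NULL
  rownames(sessions) <- NULL
  structure(list(participants = participants, sessions = sessions,
                 config = config),
            class = "wmt_cohort")
}

participants_col_classes <- c(
  id = "character", schedule = "character", treatment = "character",
  group = "character", task_order = "character", age = "numeric",
  sex = "character", completed = "logical", last_session = "integer",
  dsf_pre = "integer", dsf_post = "integer", dsb_pre = "integer",
  dsb_post = "integer", rr_pre = "integer", rr_post = "integer",
  questionnaire = "logical", likert_challenging = "integer",
  likert_engaging = "integer", likert_adopt = "integer",
  likert_schedule = "integer")

sessions_col_classes <- c(
  id = "character", task = "character", session = "integer",
  date = "character", mean_nback = "numeric")

#' Write / read a cohort as tidy CSV
#'
#' `write_cohort()` writes `participants.csv` and `sessions.csv` (UTF-8,
#' header row) to a directory; `read_cohort()` restores them with explicit
#' column classes so that a write/read round trip is exact.
#'
#' @param cohort A `wmt_cohort`.
#' @param dir Directory path (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` a
#'   `wmt_cohort` (without the generating config).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wmt_cohort") || is.list(cohort))
  if (nrow(cohort$participants) == 0L) stop("empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pfile <- file.path(dir, "participants.csv")
  sfile <- file.path(dir, "sessions.csv")
  if (!file.exists(pfile) || !file.exists(sfile)) {
    stop("cohort directory must contain participants.csv and sessions.csv")
  }
  participants <- utils::read.csv(pfile, colClasses = participants_col_classes)
  sessions <- utils::read.csv(sfile, colClasses = sessions_col_classes)
  structure(list(participants = participants, sessions = sessions,
                 config = NULL),
            class = "wmt_cohort")
}
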