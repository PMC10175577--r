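# Near-transfer (digit span) and far-transfer (relational reasoning) scoring,
# plus the simulators used by the synthetic cohort.

#' Digit-span protocol
#'
#' Protocol for the computerized digit-span tasks: two trials at each string
#' length, forward lengths 3-9, backward lengths 2-8. The string length
#' increases after at least one correct trial of the two; the task terminates
#' after both trials at a length are incorrect. The span is the maximum
#' administered length with at least one correct trial (50% of trials); if no
#' length is passed the span is scored one below the protocol minimum, a
#' floor convention that keeps the score ordinal and distinct from missing.
#'
#' @param direction `"forward"` or `"backward"`.
#' @return An object of class `span_protocol` with fields `direction`,
#'   `lengths` and `trials_per_length`.
#' @export
span_protocol <- function(direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  lengths <- if (direction == "forward") 3:9 else 2:8
  structure(list(direction = direction, lengths = lengths,
                 trials_per_length = 2L),
            class = "span_protocol")
}

#' Judge a single digit-span trial
#'
#' A forward trial is correct when the typed answer equals the presented
#' sequence verbatim; a backward trial when it equals the reversed sequence.
#' The typed answer is whitespace-stripped before comparison; any length
#' mismatch, digit difference or non-digit character scores the trial
#' incorrect (non-digit input is data, not an error).
#'
#' @param presented Integer vector of presented digits (0-9).
#' @param typed Character scalar, the participant's typed response.
#' @param direction `"forward"` or `"backward"`.
#' @return Logical scalar.
#' @examples
#' judge_span_trial(c(3, 1, 4), "314", "forward")   # TRUE
#' judge_span_trial(c(3, 1, 4), "413", "backward")  # TRUE
#' judge_span_trial(c(3, 1, 4), "31", "forward")    # FALSE
#' @export
judge_span_trial <- function(presented, typed,
                             direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(presented), all(presented %in% 0:9),
            is.character(typed), length(typed) == 1L)
  typed <- gsub("[[:space:]]", "", typed)
  if (!grepl("^[0-9]*$", typed)) return(FALSE)
  target <- if (direction == "forward") presented else rev(presented)
  identical(paste(target, collapse = ""), typed)
}

#' Score a digit-span outcome
#'
#' Applies the two-trials-per-length protocol to trial results supplied in
#' administration order, verifying that they are consistent with the stop
#' rule (administration must cover a prefix of the protocol lengths and must
#' stop exactly at the first length where both trials fail).
#'
#' @param trials Data frame with columns `length`, `correct1`, `correct2`
#'   (one row per administered length, in administration order).
#' @param protocol A [span_protocol()].
#' @return Integer span: the maximum administered length with >= 1 correct
#'   trial, or `min(protocol$lengths) - 1` when no length is passed.
#' @export
score_digit_span <- function(trials, protocol = span_protocol("forward")) {
  stopifnot(is.data.frame(trials),
            all(c("length", "correct1", "correct2") %in% names(trials)))
  n <- nrow(trials)
  if (n == 0L) stop("no trials administered")
  expected <- protocol$lengths[seq_len(n)]
  if (n > length(protocol$lengths) || !identical(as.integer(trials$length),
                                                 as.integer(expected))) {
    stop("administered lengths must form a prefix of the protocol range")
  }
  passed <- trials$correct1 | trials$correct2
  failed_at <- which(!passed)
  if (length(failed_at) > 0L && failed_at[1L] < n) {
    stop("trials continue past a double failure: protocol violation")
  }
  if (n < length(protocol$lengths) && passed[n]) {
    stop("administration stopped early without a double failure")
  }
  if (any(passed)) max(trials$length[passed]) else min(protocol$lengths) - 1L
}

#' Simulate a digit-span administration
#'
#' Plays the adaptive protocol against a latent-span responder: a trial at
#' length L is correct with probability `plogis(discrim * (latent_span - L +
#' 0.5))`. With `discrim = Inf` the responder is deterministic and passes
#' exactly the lengths `L <= latent_span`, so the recovered span equals
#' `latent_span` (clamped to the protocol range).
#'
#' @param latent_span Latent span in digits.
#' @param protocol A [span_protocol()].
#' @param discrim Logistic slope; `Inf` for a noise-free responder.
#' @return List with elements `trials` (data frame as accepted by
#'   [score_digit_span()]) and `span`.
#' @export
simulate_digit_span <- function(latent_span, protocol = span_protocol("forward"),
                                discrim = Inf) {
  lens <- protocol$lengths
  if (is.infinite(discrim)) {
    c1 <- c2 <- lens <= latent_span
  } else {
    p <- stats::plogis(discrim * (latent_span - lens + 0.5))
    c1 <- stats::runif(length(lens)) < p
    c2 <- stats::runif(length(lens)) < p
  }
  fail <- !c1 & !c2
  n_admin <- if (any(fail)) which(fail)[1L] else length(lens)
  idx <- seq_len(n_admin)
  trials <- data.frame(length = lens[idx], correct1 = c1[idx],
                       correct2 = c2[idx])
  list(trials = trials, span = score_digit_span(trials, protocol))
}

#' Score the timed relational-reasoning task
#'
#' The outcome is the number of correctly solved puzzles completed within the
#' time limit (5 minutes by default); responses finishing after the limit are
#' excluded.
#'
#' @param correct Logical vector, one entry per attempted puzzle.
#' @param elapsed Numeric vector of cumulative completion times in seconds,
#'   non-decreasing.
#' @param limit Time limit in seconds.
#' @return Integer count of correct solutions within the limit.
#' @export
score_reasoning <- function(correct, elapsed, limit = 300) {
  stopifnot(is.logical(correct), length(correct) == length(elapsed))
  if (any(elapsed < 0)) stop("elapsed times must be non-negative")
  if (is.unsorted(elapsed)) stop("elapsed times must be non-decreasing")
  sum(correct & elapsed <= limit)
}

#' Simulate the relational-reasoning task
#'
#' Items increase in difficulty through the task: item j is solved correctly
#' with probability `plogis(ability - drift * j)` and takes a log-normal time
#' whose median grows with j. The simulated participant attempts puzzles
#' until the time limit expires.
#'
#' @param ability Latent reasoning ability (logit units).
#' @param limit Time limit in seconds.
#' @param drift Per-item difficulty increment (logit units).
#' @param base_time Median solve time of the first item, seconds.
#' @return List with `responses` (data frame `correct`, `elapsed`) and
#'   `score`.
#' @export
simulate_reasoning <- function(ability, limit = 300, drift = 0.3,
                               base_time = 12) {
  # draw in chunks: a puzzle started before the limit is attempted even if
  # it finishes after it (the scorer then excludes it)
  correct <- logical(0)
  elapsed <- numeric(0)
  j0 <- 0L
  repeat {
    j <- j0 + 1:40
    times <- stats::rlnorm(40, meanlog = log(base_time * (1 + 0.04 * j)),
                           sdlog = 0.35)
    correct <- c(correct,
                 stats::runif(40) < stats::plogis(ability - drift * j))
    elapsed <- c(elapsed, (if (j0 > 0) elapsed[j0] else 0) + cumsum(times))
    if (elapsed[length(elapsed)] >= limit) break
    j0 <- j0 + 40L
  }
  n_att <- which(elapsed >= limit)[1L]
  resp <- data.frame(correct = correct[seq_len(n_att)],
                     elapsed = elapsed[seq_len(n_att)])
  list(responses = resp,
       score = score_reasoning(resp$correct, resp$elapsed, limit))
}
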