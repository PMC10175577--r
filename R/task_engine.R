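# Adaptive n-back task engine: block construction, scoring, staircase.

#' n-back task configuration
#'
#' Builds the configuration for one adaptive n-back task. The verbal variant
#' draws stimuli from eight lowercase consonants; the spatial variant from the
#' nine cells of a 3 x 3 grid. Defaults encode the standard home-based
#' training protocol: eight blocks per session, 20 critical screens per block
#' of which six are targets, a staircase that raises the load level after
#' >= 90% accuracy and lowers it after <= 70%, sessions opening with two
#' 1-back blocks and one 2-back block, and the session outcome defined as the
#' mean level of the last five blocks.
#'
#' @param modality `"verbal"` or `"spatial"`; selects the stimulus alphabet.
#' @param n_blocks Number of blocks per session.
#' @param critical_screens Number of scored screens per block (a block has
#'   `critical_screens + level` screens in total).
#' @param targets_per_block Number of target screens among the critical
#'   screens.
#' @param acc_up Accuracy at or above which the next block's level increases
#'   by one.
#' @param acc_down Accuracy at or below which the next block's level decreases
#'   by one (floored at `min_level`).
#' @param min_level Lowest admissible load level.
#' @param max_level Cap on the load level. The protocol itself imposes no
#'   ceiling; the cap only bounds simulated runs and is far above any level a
#'   human-plausible responder reaches.
#' @param start_levels Levels of the opening non-adaptive blocks; the
#'   staircase governs transitions from the last of these onwards.
#' @param outcome_window Number of final blocks averaged into the session
#'   outcome.
#' @param stim_ms,isi_ms Stimulus duration and inter-stimulus interval in
#'   milliseconds. Carried as metadata only: the engine is turn-based and
#'   simulates no wall-clock timing.
#' @return An object of class `nback_config`.
#' @examples
#' cfg <- nback_config("verbal")
#' cfg$alphabet
#' @export
nback_config <- function(modality = c("verbal", "spatial"),
                         n_blocks = 8L,
                         critical_screens = 20L,
                         targets_per_block = 6L,
                         acc_up = 0.90,
                         acc_down = 0.70,
                         min_level = 1L,
                         max_level = 12L,
                         start_levels = c(1L, 1L, 2L),
                         outcome_window = 5L,
                         stim_ms = 1000,
                         isi_ms = 2000) {
  modality <- match.arg(modality)
  alphabet <- if (modality == "verbal") {
    c("c", "g", "h", "k", "p", "q", "t", "w")
  } else {
    as.character(1:9)  # grid cells, row-major
  }
  cfg <- list(
    modality = modality,
    alphabet = alphabet,
    alphabet_size = length(alphabet),
    n_blocks = as.integer(n_blocks),
    critical_screens = as.integer(critical_screens),
    targets_per_block = as.integer(targets_per_block),
    acc_up = acc_up,
    acc_down = acc_down,
    min_level = as.integer(min_level),
    max_level = as.integer(max_level),
    start_levels = as.integer(start_levels),
    outcome_window = as.integer(outcome_window),
    stim_ms = stim_ms,
    isi_ms = isi_ms
  )
  if (cfg$acc_down >= cfg$acc_up) {
    stop("`acc_down` must be strictly below `acc_up`")
  }
  if (cfg$targets_per_block > cfg$critical_screens) {
    stop("`targets_per_block` cannot exceed `critical_screens`")
  }
  if (cfg$outcome_window > cfg$n_blocks) {
    stop("`outcome_window` cannot exceed `n_blocks`")
  }
  if (cfg$alphabet_size < 2L) {
    stop("the stimulus alphabet must contain at least two symbols")
  }
  structure(cfg, class = "nback_config")
}

#' Generate one n-back block
#'
#' Constructs the stimulus sequence for a single block at the given load
#' level. A block has `level + critical_screens` screens; the first `level`
#' screens seed the sequence and can never be targets. Target positions are
#' drawn uniformly without replacement from the critical screens and re-drawn
#' for every block. Stimuli are laid down left to right: a target screen
#' copies the stimulus `level` steps back, a critical non-target draws
#' uniformly from the alphabet excluding that single symbol (lures at other
#' lags are permitted), and seed screens draw uniformly from the full
#' alphabet.
#'
#' @param level Load level n (>= 1).
#' @param config An [nback_config()].
#' @return An object of class `nback_block` with fields `level`, `stimuli`
#'   (character vector of length `level + critical_screens`) and `is_target`
#'   (logical vector of the same length).
#' @examples
#' set.seed(1)
#' blk <- generate_block(2, nback_config("verbal"))
#' sum(blk$is_target)
#' @export
generate_block <- function(level, config = nback_config()) {
  stopifnot(inherits(config, "nback_config"))
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L) {
    stop("`level` must be a single integer >= 1")
  }
  if (config$alphabet_size < 2L) {
    stop("cannot place non-targets with an alphabet of fewer than two symbols")
  }
  n_scr <- level + config$critical_screens
  critical <- (level + 1L):n_scr
  targets <- sample(critical, config$targets_per_block)
  is_target <- rep(FALSE, n_scr)
  is_target[targets] <- TRUE

  stimuli <- character(n_scr)
  for (i in seq_len(n_scr)) {
    if (i <= level) {
      stimuli[i] <- sample(config$alphabet, 1L)
    } else if (is_target[i]) {
      stimuli[i] <- stimuli[i - level]
    } else {
      forbidden <- stimuli[i - level]
      pool <- config$alphabet[config$alphabet != forbidden]
      stimuli[i] <- pool[sample.int(length(pool), 1L)]
    }
  }
  structure(list(level = level, stimuli = stimuli, is_target = is_target),
            class = "nback_block")
}

#' Score an n-back block
#'
#' Accuracy is computed over the last `critical_screens` screens only: a hit
#' is a response at a target, a correct rejection is the absence of a response
#' at a non-target, and accuracy = (hits + correct rejections) /
#' `critical_screens`.
#'
#' @param block An `nback_block`.
#' @param responses Logical vector, one entry per screen (`TRUE` = spacebar
#'   pressed).
#' @param config An [nback_config()]; only `critical_screens` is used.
#' @return An object of class `nback_block_result` with fields `responses`
#'   and `accuracy`.
#' @export
score_block <- function(block, responses, config = nback_config()) {
  stopifnot(inherits(block, "nback_block"))
  if (!is.logical(responses) || length(responses) != length(block$stimuli) ||
      anyNA(responses)) {
    stop("`responses` must be a complete logical vector with one entry per screen")
  }
  k <- config$critical_screens
  idx <- (length(responses) - k + 1L):length(responses)
  correct <- responses[idx] == block$is_target[idx]
  structure(list(responses = responses, accuracy = sum(correct) / k),
            class = "nback_block_result")
}

#' Staircase level update
#'
#' Returns the load level of the next block given the accuracy of the current
#' one: up one level at accuracy >= `acc_up`, down one (floored at
#' `min_level`) at accuracy <= `acc_down`, otherwise unchanged. Levels are
#' capped at `max_level`.
#'
#' @param level Current load level.
#' @param accuracy Block accuracy in `[0, 1]`.
#' @param config An [nback_config()].
#' @return The next block's load level (integer).
#' @examples
#' staircase_update(2, 0.95)  # 3
#' staircase_update(1, 0.60)  # 1
#' staircase_update(3, 0.80)  # 3
#' @export
staircase_update <- function(level, accuracy, config = nback_config()) {
  stopifnot(level >= config$min_level, accuracy >= 0, accuracy <= 1)
  level <- as.integer(level)
  if (accuracy >= config$acc_up) {
    min(level + 1L, config$max_level)
  } else if (accuracy <= config$acc_down) {
    max(level - 1L, config$min_level)
  } else {
    level
  }
}

#' Run one adaptive training session
#'
#' Plays the eight blocks of one session against a responder. The session
#' opens with the fixed `start_levels` (two 1-back blocks then a 2-back
#' block); from there each block's level follows [staircase_update()] applied
#' to the previous block's accuracy. The session outcome is the mean load
#' level of the final `outcome_window` blocks.
#'
#' @param responder A function `(block) -> logical vector` giving the
#'   response at every screen. See [responder_logistic()],
#'   [responder_perfect()], [responder_mute()].
#' @param config An [nback_config()].
#' @return An object of class `nback_session` with fields `levels`,
#'   `accuracies` (each length `n_blocks`) and `outcome`.
#' @examples
#' run_session(responder_perfect())$outcome  # 5
#' @export
run_session <- function(responder, config = nback_config()) {
  stopifnot(is.function(responder))
  nb <- config$n_blocks
  levels <- integer(nb)
  accuracies <- numeric(nb)
  n_start <- length(config$start_levels)
  for (b in seq_len(nb)) {
    levels[b] <- if (b <= n_start) {
      config$start_levels[b]
    } else {
      staircase_update(levels[b - 1L], accuracies[b - 1L], config)
    }
    block <- generate_block(levels[b], config)
    resp <- responder(block)
    if (!is.logical(resp) || length(resp) != length(block$stimuli) ||
        anyNA(resp)) {
      stop("responder returned a malformed response sequence")
    }
    accuracies[b] <- score_block(block, resp, config)$accuracy
  }
  win <- (nb - config$outcome_window + 1L):nb
  structure(list(levels = levels, accuracies = accuracies,
                 outcome = mean(levels[win])),
            class = "nback_session")
}

#' Responders
#'
#' Response policies for simulated sessions. `responder_perfect()` always
#' responds correctly; `responder_mute()` never presses (yielding 14/20 = 0.70
#' accuracy, which drives the staircase down); `responder_logistic()` models a
#' learner with working memory capacity `capacity`: on every screen the
#' probability of acting correctly (pressing at a target, withholding at a
#' non-target) is `lapse/2 + (1 - lapse) * plogis(discrim * (capacity -
#' level))`, so performance degrades smoothly as the load level exceeds
#' capacity.
#'
#' @param capacity Latent capacity in load-level units.
#' @param discrim Logistic slope per load-level unit; larger values give a
#'   sharper transition from mastery to failure around `capacity`.
#' @param lapse Lapse rate in `[0, 0.2]`: the fraction of screens answered at
#'   chance regardless of load.
#' @return A function `(block) -> logical vector` usable with
#'   [run_session()].
#' @export
responder_logistic <- function(capacity, discrim = 3, lapse = 0.05) {
  stopifnot(lapse >= 0, lapse <= 0.2)
  function(block) {
    p_correct <- lapse / 2 + (1 - lapse) *
      stats::plogis(discrim * (capacity - block$level))
    act_correct <- stats::runif(length(block$stimuli)) < p_correct
    ifelse(act_correct, block$is_target, !block$is_target)
  }
}

#' @rdname responder_logistic
#' @export
responder_perfect <- function() {
  function(block) block$is_target
}

#' @rdname responder_logistic
#' @export
responder_mute <- function() {
  function(block) rep(FALSE, length(block$stimuli))
}

#' JSON serialization for blocks and sessions
#'
#' Round-trip-exact JSON encoding of `nback_block` and `nback_session`
#' objects.
#'
#' @param x An `nback_block` or `nback_session`.
#' @param json A JSON string produced by the matching `*_to_json()`.
#' @return `*_to_json()` returns a JSON string; `*_from_json()` the restored
#'   object.
#' @export
block_to_json <- function(x) {
  stopifnot(inherits(x, "nback_block"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname block_to_json
#' @export
block_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(level = as.integer(x$level),
                 stimuli = as.character(x$stimuli),
                 is_target = as.logical(x$is_target)),
            class = "nback_block")
}

#' @rdname block_to_json
#' @export
session_to_json <- function(x) {
  stopifnot(inherits(x, "nback_session"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname block_to_json
#' @export
session_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(levels = as.integer(x$levels),
                 accuracies = as.numeric(x$accuracies),
                 outcome = as.numeric(x$outcome)),
            class = "nback_session")
}
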