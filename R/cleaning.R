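#' Cleaning configuration
#'
#' Bundles the trial- and participant-level cleaning options. The latency
#' thresholds (300 ms fast-trial mark, 400 ms lower-tail deletion, 10,000 ms
#' slow-trial removal) and the 10% fast-participant threshold are fixed
#' conventions of the D-score family; only accuracy cleaning, its error
#' threshold, and speed cleaning are user choices. All thresholds are strict
#' inequalities: a trial at exactly 10,000 ms is retained, a participant at
#' exactly 25% errors or exactly 10% fast trials is not excluded.
#'
#' @param accuracy_cleaning Logical; exclude participants whose error
#'   percentage in at least one mapping condition exceeds `error_threshold`.
#' @param error_threshold Percent, strictly between 0 and 100 (default 25).
#' @param speed_cleaning Logical; exclude participants with more than 10% of
#'   trials faster than 300 ms.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(accuracy_cleaning = FALSE,
                            error_threshold = 25,
                            speed_cleaning = FALSE) {
  if (!is.numeric(error_threshold) || length(error_threshold) != 1 ||
      error_threshold <= 0 || error_threshold >= 100) {
    stop("`error_threshold` must be a percentage strictly between 0 and 100",
         call. = FALSE)
  }
  structure(
    list(
      accuracy_cleaning = isTRUE(accuracy_cleaning),
      error_threshold = error_threshold,
      speed_cleaning = isTRUE(speed_cleaning),
      fast_participant_threshold = 10,
      fast_trial_ms = 300,
      slow_trial_ms = 10000,
      lower_tail_ms = 400
    ),
    class = "cleaning_config"
  )
}

# Per-participant counts over all participants in `ids` (0 when absent),
# preserving first-appearance order.
count_by_participant <- function(participant, ids) {
  counts <- stats::setNames(integer(length(ids)), ids)
  tab <- table(participant)
  counts[names(tab)] <- as.integer(tab)
  counts
}

participant_ids <- function(trials) unique(trials$participant)

#' Remove trials slower than 10,000 ms
#'
#' Drops every trial with latency strictly above 10,000 ms (all algorithms
#' apply this step) and records how many were dropped per participant.
#'
#' @param trials An `iat_trials` table.
#' @return A list with `trials` (the filtered table) and `counts` (named
#'   integer vector of removed trials per participant, 0 included).
#' @export
remove_slow_trials <- function(trials) {
  stopifnot(inherits(trials, "iat_trials"))
  ids <- participant_ids(trials)
  slow <- trials$latency > 10000
  list(
    trials = keep_trial_attrs(trials[!slow, , drop = FALSE], trials),
    counts = count_by_participant(trials$participant[slow], ids)
  )
}

#' Remove lower-tail trials (< 400 ms) when the algorithm calls for it
#'
#' Algorithms D2, D5 and D6 delete trials with latency strictly below 400 ms
#' before scoring; D1, D3 and D4 do not. When the deletion does not apply,
#' the table is returned unchanged and the counts are `NA` ("not expected for
#' this D").
#'
#' @param trials An `iat_trials` table, slow trials already removed.
#' @param algorithm Algorithm id, number or spec (see [algorithm_spec()]).
#' @return A list with `trials`, `counts` (removed per participant, or `NA`s
#'   when not applicable) and `applicable` (logical).
#' @export
remove_lower_tail <- function(trials, algorithm) {
  stopifnot(inherits(trials, "iat_trials"))
  alg <- algorithm_spec(algorithm)
  ids <- participant_ids(trials)
  if (!alg$lower_tail_deletion) {
    return(list(
      trials = trials,
      counts = stats::setNames(rep(NA_integer_, length(ids)), ids),
      applicable = FALSE
    ))
  }
  fast <- trials$latency < 400
  list(
    trials = keep_trial_attrs(trials[!fast, , drop = FALSE], trials),
    counts = count_by_participant(trials$participant[fast], ids),
    applicable = TRUE
  )
}

#' Count trials faster than a latency threshold, per participant
#'
#' Used for the `num.300` and `num.400` diagnostic columns; the threshold is
#' strict (a trial at exactly the threshold is not counted).
#'
#' @param trials An `iat_trials` table.
#' @param threshold_ms Latency threshold in milliseconds.
#' @return Named integer vector, one entry per participant.
#' @export
count_fast_trials <- function(trials, threshold_ms) {
  stopifnot(inherits(trials, "iat_trials"))
  ids <- participant_ids(trials)
  fast <- trials$latency < threshold_ms
  count_by_participant(trials$participant[fast], ids)
}

#' Flag participants with too many errors in either condition
#'
#' A participant is flagged when the percentage of incorrect trials, pooled
#' over all Mapping A trials or over all Mapping B trials, strictly exceeds
#' the error threshold (default 25%). Flagged participants are withheld from
#' displayed summaries but never dropped from the results table.
#'
#' @param trials An `iat_trials` table (post slow-trial removal).
#' @param config A [cleaning_config()]. The flag is all-`FALSE` when
#'   `accuracy_cleaning` is off.
#' @return Named logical vector per participant.
#' @export
flag_inaccurate_participants <- function(trials, config = cleaning_config()) {
  stopifnot(inherits(trials, "iat_trials"))
  ids <- participant_ids(trials)
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!config$accuracy_cleaning) return(flags)
  err_pct <- tapply(
    trials$correct,
    list(trials$participant, trials$condition),
    function(x) 100 * mean(x == 0)
  )
  worst <- apply(err_pct, 1, max, na.rm = TRUE)
  flags[names(worst)] <- worst > config$error_threshold
  flags
}

#' Flag participants with more than 10% of trials faster than 300 ms
#'
#' @param trials An `iat_trials` table (post slow-trial removal).
#' @param config A [cleaning_config()]. The flag is all-`FALSE` when
#'   `speed_cleaning` is off.
#' @return Named logical vector per participant.
#' @export
flag_fast_participants <- function(trials, config = cleaning_config()) {
  stopifnot(inherits(trials, "iat_trials"))
  ids <- participant_ids(trials)
  flags <- stats::setNames(rep(FALSE, length(ids)), ids)
  if (!config$speed_cleaning) return(flags)
  n_fast <- count_fast_trials(trials, config$fast_trial_ms)
  n_tot <- count_by_participant(trials$participant, ids)
  flags[] <- 100 * n_fast[ids] / n_tot[ids] > config$fast_participant_threshold
  flags
}
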