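#' Configuration for the synthetic IAT generator
#'
#' Describes a simulated IAT administration with four critical blocks per
#' participant (practice/test x Mapping A/B). Latencies follow an
#' ex-Gaussian model -- a Gaussian component (`mu`, `sigma`) plus an
#' exponential tail (`tau`) -- the standard description of response-time
#' distributions. A condition effect of `effect_delta` ms is added to every
#' Mapping B trial, so a positive delta slows Mapping B responding and
#' produces a positive B - A D-score. Error trials are drawn per condition;
#' under `builtin_correction` their latencies are additionally inflated by
#' `correction_penalty_ms`, emulating administrations where an error must be
#' corrected before the task continues. Optional contamination injects
#' implausibly fast (< 300 ms) and slow (> 10,000 ms) trials so the cleaning
#' rules have something to catch.
#'
#' @param n_participants Number of simulated participants.
#' @param trials_practice Trials in each practice block (default 20).
#' @param trials_test Trials in each test block (default 40).
#' @param mu,sigma,tau Ex-Gaussian parameters in ms (defaults 600, 100, 150).
#' @param effect_delta Condition effect in ms added to Mapping B latencies
#'   (default 0).
#' @param error_rate_A,error_rate_B Per-trial error probability in each
#'   condition (default 0.05).
#' @param builtin_correction Logical; inflate error latencies at source.
#' @param correction_penalty_ms Added to error latencies when
#'   `builtin_correction` is on (default 400 ms).
#' @param fast_trial_rate,slow_trial_rate Probability that a trial is
#'   replaced by a contaminant below 300 ms / above 10,000 ms (default 0).
#' @param seed Integer seed; identical seed and config give an identical
#'   data set.
#' @return An object of class `iat_simconfig`.
#' @export
simulation_config <- function(n_participants,
                              trials_practice = 20, trials_test = 40,
                              mu = 600, sigma = 100, tau = 150,
                              effect_delta = 0,
                              error_rate_A = 0.05, error_rate_B = 0.05,
                              builtin_correction = FALSE,
                              correction_penalty_ms = 400,
                              fast_trial_rate = 0, slow_trial_rate = 0,
                              seed = NULL) {
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1) {
      stop("`", nm, "` must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (n_participants < 1 || trials_practice < 1 || trials_test < 1) {
    stop("participant and trial counts must be >= 1", call. = FALSE)
  }
  if (sigma <= 0 || tau <= 0) stop("sigma and tau must be > 0", call. = FALSE)
  chk_rate(error_rate_A, "error_rate_A")
  chk_rate(error_rate_B, "error_rate_B")
  chk_rate(fast_trial_rate, "fast_trial_rate")
  chk_rate(slow_trial_rate, "slow_trial_rate")
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_practice = as.integer(trials_practice),
      trials_test = as.integer(trials_test),
      mu = mu, sigma = sigma, tau = tau,
      effect_delta = effect_delta,
      error_rate_A = error_rate_A, error_rate_B = error_rate_B,
      builtin_correction = isTRUE(builtin_correction),
      correction_penalty_ms = correction_penalty_ms,
      fast_trial_rate = fast_trial_rate, slow_trial_rate = slow_trial_rate,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "iat_simconfig"
  )
}

# Ex-Gaussian draws: Gaussian(mu, sigma) + Exponential(mean tau), floored at
# 1 ms (the Gaussian component can stray below zero at extreme quantiles).
rexgauss <- function(n, mu, sigma, tau) {
  pmax(stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau), 1)
}

#' Generate a synthetic trial-level IAT data set
#'
#' Draws a full data set in the standard input schema (`participant`,
#' `block`, `latency`, `correct`) with blocks labeled `practiceMappingA`,
#' `testMappingA`, `practiceMappingB`, `testMappingB`, and returns it
#' together with the ground truth that produced it so recovery can be
#' asserted without re-parsing the trials.
#'
#' @param config An [simulation_config()] object.
#' @return An object of class `iat_simulation`: a list with `trials` (data
#'   frame, one row per trial) and `truth` (the configuration used,
#'   including `effect_delta`, rates and seed).
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_participants = 2, seed = 1))
#' nrow(sim$trials)  # 2 * (20 + 40 + 20 + 40)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "iat_simconfig"))
  if (!is.null(config$seed)) set.seed(config$seed)

  blocks <- data.frame(
    block = c("practiceMappingA", "testMappingA",
              "practiceMappingB", "testMappingB"),
    condition = c("MappingA", "MappingA", "MappingB", "MappingB"),
    n = c(config$trials_practice, config$trials_test,
          config$trials_practice, config$trials_test),
    stringsAsFactors = FALSE
  )
  n_per_part <- sum(blocks$n)
  width <- max(2, nchar(as.character(config$n_participants)))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(config$n_participants))

  per_participant <- function(id) {
    block <- rep(blocks$block, blocks$n)
    condition <- rep(blocks$condition, blocks$n)
    latency <- rexgauss(n_per_part, config$mu, config$sigma, config$tau)
    latency[condition == "MappingB"] <-
      latency[condition == "MappingB"] + config$effect_delta
    err_p <- ifelse(condition == "MappingA",
                    config$error_rate_A, config$error_rate_B)
    correct <- as.integer(stats::runif(n_per_part) >= err_p)
    if (config$builtin_correction) {
      latency[correct == 0] <-
        latency[correct == 0] + config$correction_penalty_ms
    }
    u <- stats::runif(n_per_part)
    is_fast <- u < config$fast_trial_rate
    is_slow <- !is_fast &
      u < config$fast_trial_rate + config$slow_trial_rate
    latency[is_fast] <- stats::runif(sum(is_fast), 50, 299)
    latency[is_slow] <- stats::runif(sum(is_slow), 10001, 15000)
    data.frame(participant = id, block = block, latency = round(latency, 2),
               correct = correct, stringsAsFactors = FALSE)
  }

  trials <- do.call(rbind, lapply(ids, per_participant))
  rownames(trials) <- NULL
  structure(
    list(trials = trials, truth = unclass(config)),
    class = "iat_simulation"
  )
}

#' Write a simulated data set with its ground-truth sidecar
#'
#' Writes the trials as a standard input CSV and the generating parameters
#' as a JSON sidecar (`<path>.truth.json`), so downstream checks never need
#' to infer the truth from the trials themselves.
#'
#' @param sim An `iat_simulation` from [generate_dataset()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  stopifnot(inherits(sim, "iat_simulation"))
  utils::write.csv(sim$trials, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Effect-recovery sweep over a grid of condition effects
#'
#' For each requested condition effect, generates a fresh data set, scores it
#' with each algorithm, and records the mean D-score over participants. With
#' everything else equal, the mean D-score must grow with the simulated
#' effect; a non-monotone column signals a scoring defect (a warning is
#' raised and the `monotone` attribute set accordingly).
#'
#' @param deltas Numeric vector (length >= 2) of condition effects in ms.
#' @param config Base [simulation_config()]; its `effect_delta` is replaced
#'   by each delta in turn and its seed offset per delta so data sets are
#'   independent.
#' @param algorithms Algorithm ids to sweep (default all six).
#' @return A data frame with one row per delta and one column per algorithm
#'   holding the mean D-score, plus attribute `monotone` (logical per
#'   algorithm: non-decreasing in delta).
#' @export
recovery_suite <- function(deltas, config,
                           algorithms = paste0("D", 1:6)) {
  stopifnot(inherits(config, "iat_simconfig"), length(deltas) >= 2)
  means <- matrix(NA_real_, nrow = length(deltas), ncol = length(algorithms),
                  dimnames = list(NULL, algorithms))
  for (i in seq_along(deltas)) {
    cfg <- config
    cfg$effect_delta <- deltas[i]
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + i - 1L
    sim <- generate_dataset(cfg)
    trials <- validate_trials(sim$trials,
                              builtin_corrected = cfg$builtin_correction)
    for (a in algorithms) {
      res <- score_dataset(trials, a)
      means[i, a] <- mean(res[[score_columns(res)[["dscore"]]]], na.rm = TRUE)
    }
  }
  monotone <- apply(means, 2, function(x) !is.unsorted(x))
  if (!all(monotone)) {
    warning("mean D-score not monotone in the simulated effect for: ",
            paste(algorithms[!monotone], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(delta = deltas, means, check.names = FALSE)
  attr(out, "monotone") <- monotone
  out
}
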