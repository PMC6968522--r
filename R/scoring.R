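#' D-score algorithm specifications
#'
#' The six classical D-score algorithms combine an error-inflation strategy
#' with an optional lower-tail deletion:
#'
#' | id | error inflation                  | delete trials < 400 ms |
#' |----|----------------------------------|------------------------|
#' | D1 | built-in correction              | no                     |
#' | D2 | built-in correction              | yes                    |
#' | D3 | mean(correct) + 2 SD             | no                     |
#' | D4 | mean(correct) + 600 ms           | no                     |
#' | D5 | mean(correct) + 2 SD             | yes                    |
#' | D6 | mean(correct) + 600 ms           | yes                    |
#'
#' Built-in inflation (D1/D2) leaves latencies untouched: it assumes the
#' recorded latency of an error trial already includes the time the
#' respondent took to correct it. The ex-post strategies (D3-D6) replace each
#' error latency with the mean correct-trial latency of the block in which
#' the error occurred plus a penalty: 600 ms, or twice the block's
#' correct-trial standard deviation.
#'
#' @param algorithm One of `"D1"`..`"D6"` (case-insensitive), an integer 1-6,
#'   or an existing spec (returned unchanged).
#' @return An object of class `iat_algorithm`: a list with `id`, `number`,
#'   `error_inflation` (`"builtin"`, `"mean_plus_2sd"` or `"mean_plus_600"`)
#'   and `lower_tail_deletion` (logical).
#' @export
#' @examples
#' algorithm_spec("D5")
#' algorithm_spec(3)$error_inflation
algorithm_spec <- function(algorithm) {
  if (inherits(algorithm, "iat_algorithm")) return(algorithm)
  if (is.numeric(algorithm)) algorithm <- paste0("D", algorithm)
  id <- toupper(as.character(algorithm))
  defs <- list(
    D1 = list(error_inflation = "builtin",       lower_tail_deletion = FALSE),
    D2 = list(error_inflation = "builtin",       lower_tail_deletion = TRUE),
    D3 = list(error_inflation = "mean_plus_2sd", lower_tail_deletion = FALSE),
    D4 = list(error_inflation = "mean_plus_600", lower_tail_deletion = FALSE),
    D5 = list(error_inflation = "mean_plus_2sd", lower_tail_deletion = TRUE),
    D6 = list(error_inflation = "mean_plus_600", lower_tail_deletion = TRUE)
  )
  if (!id %in% names(defs)) {
    stop("unknown algorithm '", algorithm, "'; expected D1..D6", call. = FALSE)
  }
  structure(
    c(list(id = id, number = as.integer(sub("D", "", id))), defs[[id]]),
    class = "iat_algorithm"
  )
}

# Signal that a participant's score component cannot be computed. Raised as a
# classed condition so batch scoring can record the reason instead of aborting.
undefined_component <- function(reason) {
  stop(structure(
    class = c("iatdscore_undefined", "error", "condition"),
    list(message = reason, call = NULL)
  ))
}

#' Inflate error-trial latencies within one block
#'
#' Applies the error-inflation strategy of an algorithm to the trials of a
#' single block. `builtin` returns the latencies unchanged (they are assumed
#' to already include correction time); `mean_plus_600` replaces each error
#' latency with the block's mean correct latency plus 600 ms;
#' `mean_plus_2sd` replaces it with the mean plus twice the sample standard
#' deviation of the correct latencies. Correct trials are never altered.
#'
#' @param latency Numeric vector of trial latencies (ms), already filtered.
#' @param correct Integer vector of 0/1 accuracy codes, same length.
#' @param strategy `"builtin"`, `"mean_plus_2sd"` or `"mean_plus_600"`.
#' @return Numeric vector of post-inflation latencies.
#'   Raises a classed `iatdscore_undefined` condition when an ex-post
#'   strategy has no correct trial to estimate the mean from (or fewer than
#'   two for the 2 SD penalty).
#' @export
#' @examples
#' inflate_errors(c(500, 700, 650), c(1, 1, 0), "mean_plus_600")  # 650 -> 1200
inflate_errors <- function(latency, correct,
                           strategy = c("builtin", "mean_plus_2sd",
                                        "mean_plus_600")) {
  strategy <- match.arg(strategy)
  stopifnot(length(latency) == length(correct))
  if (strategy == "builtin") return(latency)
  is_err <- correct == 0
  if (!any(is_err)) return(latency)
  ok <- latency[!is_err]
  if (length(ok) == 0) undefined_component("no_correct_trials_in_block")
  penalty <- if (strategy == "mean_plus_600") {
    600
  } else {
    if (length(ok) < 2) undefined_component("single_correct_trial_in_block")
    2 * stats::sd(ok)
  }
  latency[is_err] <- mean(ok) + penalty
  latency
}

#' Pooled standard deviation of two blocks
#'
#' The sample standard deviation (n - 1 denominator) of the concatenated
#' post-inflation latencies of the two blocks entering a D component.
#'
#' @param latencies_x,latencies_y Numeric latency vectors (ms).
#' @return A single number (ms). Raises `iatdscore_undefined` when fewer than
#'   two trials are pooled or the pooled variance is zero.
#' @export
#' @examples
#' pooled_sd(c(500, 700), c(700, 900))  # 163.2993
pooled_sd <- function(latencies_x, latencies_y) {
  pooled <- c(latencies_x, latencies_y)
  if (length(pooled) < 2) undefined_component("fewer_than_two_pooled_trials")
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) undefined_component("zero_pooled_variance")
  s
}

#' One D component: standardized block-mean difference
#'
#' The mean latency difference between the Mapping B and Mapping A block of a
#' pair (practice or test), divided by the standard deviation of the pooled
#' trials of both blocks. The default direction is B - A, so a positive
#' component means slower responding under Mapping B; the reversed direction
#' is an exact sign flip.
#'
#' @param block_A,block_B Post-inflation latency vectors for the Mapping A
#'   and Mapping B block of the pair.
#' @param direction `"B-A"` (default) or `"A-B"`.
#' @return A single standardized value.
#' @export
#' @examples
#' d_component(c(500, 700), c(700, 900))  # 1.224745
d_component <- function(block_A, block_B, direction = c("B-A", "A-B")) {
  direction <- match.arg(direction)
  if (length(block_A) == 0 || length(block_B) == 0) {
    undefined_component("empty_block")
  }
  d <- (mean(block_B) - mean(block_A)) / pooled_sd(block_A, block_B)
  if (direction == "A-B") -d else d
}

#' Classify a D-score into effect-size bands
#'
#' Uses the conventional interpretation bands at |d| = 0.15, 0.35 and 0.65:
#' below 0.15 the association is negligible, then slight, moderate, and
#' strong from 0.65 up. The sign (which mapping was faster) is carried
#' separately.
#'
#' @param dscore Numeric vector of D-scores (`NA` allowed).
#' @return A data frame with columns `magnitude` (factor: negligible, slight,
#'   moderate, strong) and `sign` (`"positive"`, `"negative"` or `"zero"`).
#' @export
#' @examples
#' classify_effect_size(c(0.7, -0.4, 0.05))
classify_effect_size <- function(dscore) {
  magnitude <- cut(
    abs(dscore),
    breaks = c(-Inf, 0.15, 0.35, 0.65, Inf),
    labels = c("negligible", "slight", "moderate", "strong"),
    right = FALSE
  )
  sgn <- ifelse(is.na(dscore), NA_character_,
                ifelse(dscore > 0, "positive",
                       ifelse(dscore < 0, "negative", "zero")))
  data.frame(magnitude = magnitude, sign = sgn)
}

# Compute one participant's components from a list of per-role latency/correct
# vectors. Returns d_practice, d_test, dscore and a reason string (NA if ok).
score_blocks <- function(blocks, alg, direction) {
  comp <- function(role_A, role_B) {
    infl <- function(role) {
      inflate_errors(blocks[[role]]$latency, blocks[[role]]$correct,
                     alg$error_inflation)
    }
    d_component(infl(role_A), infl(role_B), direction)
  }
  reasons <- character(0)
  d_prac <- tryCatch(comp("practice_A", "practice_B"),
                     iatdscore_undefined = function(e) {
                       reasons <<- c(reasons, paste0("practice:", conditionMessage(e)))
                       NA_real_
                     })
  d_test <- tryCatch(comp("test_A", "test_B"),
                     iatdscore_undefined = function(e) {
                       reasons <<- c(reasons, paste0("test:", conditionMessage(e)))
                       NA_real_
                     })
  list(
    d_practice = d_prac,
    d_test = d_test,
    dscore = (d_prac + d_test) / 2,
    reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_
  )
}

#' Score a single participant's cleaned trials
#'
#' Computes the practice component (practice blocks), the test component
#' (test blocks) and their average, the D-score, for one participant whose
#' trials have already passed the trial-level filters (slow-trial removal
#' and, for D2/D5/D6, the lower-tail deletion -- see [score_dataset()] for
#' the full pipeline). Undefined components (empty block, no correct trials
#' for an ex-post strategy, zero pooled variance) yield `NA` with a
#' machine-readable reason rather than an error.
#'
#' @param trials An `iat_trials` table holding one participant's trials.
#' @param algorithm Algorithm id, number or spec.
#' @param direction `"B-A"` (default) or `"A-B"`.
#' @return A list with `d_practice`, `d_test`, `dscore` and `reason`
#'   (`NA_character_` when all components are defined).
#' @export
score_participant <- function(trials, algorithm, direction = c("B-A", "A-B")) {
  stopifnot(inherits(trials, "iat_trials"))
  direction <- match.arg(direction)
  if (length(unique(trials$participant)) > 1) {
    stop("`trials` must contain a single participant; use score_dataset()",
         call. = FALSE)
  }
  alg <- algorithm_spec(algorithm)
  blocks <- lapply(stats::setNames(BLOCK_ROLES, BLOCK_ROLES), function(role) {
    sub <- trials[trials$block_role == role, , drop = FALSE]
    list(latency = sub$latency, correct = sub$correct)
  })
  score_blocks(blocks, alg, direction)
}

# Post-inflation latencies for every retained trial of a participant, in
# table order; NULL when some block's inflation is undefined.
inflate_participant <- function(sub, alg) {
  out <- sub$latency
  for (role in BLOCK_ROLES) {
    idx <- which(sub$block_role == role)
    if (length(idx) == 0) next
    lat <- tryCatch(
      inflate_errors(sub$latency[idx], sub$correct[idx], alg$error_inflation),
      iatdscore_undefined = function(e) NULL
    )
    if (is.null(lat)) return(NULL)
    out[idx] <- lat
  }
  out
}

prop_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x == 1)
mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Score a full trial table with one D-score algorithm
#'
#' Runs the complete scoring pipeline over every participant:
#'
#' 1. remove trials slower than 10,000 ms;
#' 2. count trials below 300 ms and 400 ms and evaluate the participant-level
#'    exclusion flags (speed and accuracy) on the remaining trials;
#' 3. delete trials faster than 400 ms when the algorithm calls for it;
#' 4. inflate error latencies per the algorithm's strategy and compute the
#'    practice and test components and their average, the D-score.
#'
#' Participants flagged for exclusion are scored and kept in the output
#' (flags only gate the displayed summaries). Per-participant diagnostics
#' (trial counts, mean post-inflation latency, proportion correct per block,
#' block pool and condition, presentation order, and the raw labels behind
#' each mapping) fill the remaining result-file columns.
#'
#' @param trials A validated `iat_trials` table ([validate_trials()]).
#' @param algorithm Algorithm id (`"D1"`..`"D6"`), number, or spec.
#' @param direction `"B-A"` (default, positive = slower under Mapping B) or
#'   `"A-B"` (exact sign flip).
#' @param cleaning A [cleaning_config()].
#' @return A `dscore_results` data frame, one row per participant in order of
#'   first appearance, with the 21 standard result columns (D columns
#'   numbered after the algorithm) plus `excluded_accuracy`,
#'   `excluded_speed`, `excluded`, `effect_size`, `effect_sign` and `reason`.
#'   Attributes: `algorithm`, `direction`, `cleaning`, `roles`,
#'   `cleaned_trials` (the retained trials with a `latency_infl` column,
#'   consumed by [compute_descriptives()]), `lower_tail_applicable`, and the
#'   table-level totals `removed_slow_total` and `removed_lower_total`.
#' @export
#' @examples
#' sim <- generate_dataset(simulation_config(n_participants = 5, seed = 7))
#' trials <- validate_trials(sim$trials)
#' res <- score_dataset(trials, "D3")
#' res[, c("participant", "dscore.3")]
score_dataset <- function(trials, algorithm, direction = c("B-A", "A-B"),
                          cleaning = cleaning_config()) {
  stopifnot(inherits(trials, "iat_trials"))
  if (nrow(trials) == 0) stop("`trials` is empty", call. = FALSE)
  direction <- match.arg(direction)
  alg <- algorithm_spec(algorithm)
  ids <- participant_ids(trials)

  n_trial <- count_by_participant(trials$participant, ids)
  slow <- remove_slow_trials(trials)
  t_noslow <- slow$trials
  num_300 <- count_fast_trials(t_noslow, 300)
  num_400 <- count_fast_trials(t_noslow, 400)
  excl_speed <- flag_fast_participants(t_noslow, cleaning)
  excl_acc <- flag_inaccurate_participants(t_noslow, cleaning)
  lower <- remove_lower_tail(t_noslow, alg)
  t_clean <- lower$trials

  # condition of each participant's first trial in file order
  first_row <- !duplicated(trials$participant)
  cond_ord <- stats::setNames(
    paste0(trials$condition[first_row], "_first"),
    trials$participant[first_row]
  )

  roles <- attr(trials, "roles")
  legend_A <- paste(roles[["practice_A"]], roles[["test_A"]], sep = "_and_")
  legend_B <- paste(roles[["practice_B"]], roles[["test_B"]], sep = "_and_")

  t_clean$latency_infl <- t_clean$latency
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    sel <- t_clean$participant == id
    sub <- t_clean[sel, , drop = FALSE]
    sc <- score_participant(keep_trial_attrs(sub, trials), alg, direction)
    infl <- inflate_participant(sub, alg)
    if (!is.null(infl)) t_clean$latency_infl[sel] <- infl

    role_prop <- vapply(BLOCK_ROLES, function(role) {
      prop_or_na(sub$correct[sub$block_role == role])
    }, numeric(1))
    in_practice <- sub$block_role %in% c("practice_A", "practice_B")
    in_A <- sub$condition == "MappingA"

    rows[[i]] <- data.frame(
      participant = id,
      n_trial = n_trial[[id]],
      slow10000 = slow$counts[[id]],
      num.300 = num_300[[id]],
      num.400 = num_400[[id]],
      mean.tot = if (is.null(infl)) mean_or_na(sub$latency) else mean_or_na(infl),
      p_correct_block.practice.MappingA = role_prop[["practice_A"]],
      p_correct_block.practice.MappingB = role_prop[["practice_B"]],
      p_correct_block.test.MappingA = role_prop[["test_A"]],
      p_correct_block.test.MappingB = role_prop[["test_B"]],
      p_correct_bpool.practice = prop_or_na(sub$correct[in_practice]),
      p_correct_bpool.test = prop_or_na(sub$correct[!in_practice]),
      prop_correct_cond_MappingA = prop_or_na(sub$correct[in_A]),
      prop_correct_cond_MappingB = prop_or_na(sub$correct[!in_A]),
      p_correct_tot = prop_or_na(sub$correct),
      d_practice = sc$d_practice,
      d_test = sc$d_test,
      dscore = sc$dscore,
      cond_ord = cond_ord[[id]],
      LegendMappingA = legend_A,
      LegendMappingB = legend_B,
      reason = sc$reason,
      stringsAsFactors = FALSE,
      check.names = FALSE
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  eff <- classify_effect_size(res$dscore)
  res$effect_size <- as.character(eff$magnitude)
  res$effect_sign <- eff$sign
  res$excluded_accuracy <- unname(excl_acc[res$participant])
  res$excluded_speed <- unname(excl_speed[res$participant])
  res$excluded <- res$excluded_accuracy | res$excluded_speed

  dcols <- c("d_practice", "d_test", "dscore")
  names(res)[match(dcols, names(res))] <- paste0(dcols, ".", alg$number)

  structure(
    res,
    algorithm = alg,
    direction = direction,
    cleaning = cleaning,
    roles = roles,
    cleaned_trials = keep_trial_attrs(t_clean, trials),
    lower_tail_applicable = lower$applicable,
    removed_slow_total = sum(slow$counts),
    removed_lower_total = if (lower$applicable) sum(lower$counts) else NA_integer_,
    class = c("dscore_results", "data.frame")
  )
}

# Names of the three D columns of a results table.
score_columns <- function(results) {
  n <- attr(results, "algorithm")$number
  stats::setNames(paste0(c("d_practice.", "d_test.", "dscore."), n),
                  c("d_practice", "d_test", "dscore"))
}

#' @export
print.dscore_results <- function(x, ...) {
  alg <- attr(x, "algorithm")
  if (is.null(alg)) {  # subsetting keeps the class but drops the metadata
    print(as.data.frame(x), ...)
    return(invisible(x))
  }
  cat("D-score results: ", nrow(x), " participants, algorithm ", alg$id,
      " (", alg$error_inflation,
      if (alg$lower_tail_deletion) ", lower-tail deletion" else "",
      "), direction ", attr(x, "direction"), "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
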