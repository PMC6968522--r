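# Rows of a results table that enter displayed summaries.
displayed_rows <- function(results, include_excluded) {
  if (include_excluded) rep(TRUE, nrow(results)) else !results$excluded
}

#' Six-number summaries of the D components and D-score
#'
#' Minimum, first quartile, median, mean, third quartile and maximum of
#' `d_practice`, `d_test` and `dscore` over the sample. Participants flagged
#' for exclusion are withheld by default, mirroring the displayed summaries;
#' they always remain in the results table itself. Quartiles use linear
#' interpolation between order statistics (R's default quantile type).
#'
#' @param results A `dscore_results` object.
#' @param include_excluded Logical; include flagged participants.
#' @return A data frame with rows `Min.`, `1st Qu.`, `Median`, `Mean`,
#'   `3rd Qu.`, `Max.` and columns `d_practice`, `d_test`, `dscore`.
#' @export
summarize_scores <- function(results, include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"))
  keep <- displayed_rows(results, include_excluded)
  cols <- score_columns(results)
  six <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(rep(NA_real_, 6))
    c(min(x), stats::quantile(x, 0.25, names = FALSE), stats::median(x),
      mean(x), stats::quantile(x, 0.75, names = FALSE), max(x))
  }
  vals <- vapply(cols, function(cl) six(results[[cl]][keep]), numeric(6))
  if (all(is.na(vals))) stop("no defined scores to summarize", call. = FALSE)
  out <- as.data.frame(vals)
  names(out) <- names(cols)
  rownames(out) <- c("Min.", "1st Qu.", "Median", "Mean", "3rd Qu.", "Max.")
  out
}

#' Practice-test reliability
#'
#' The Pearson product-moment correlation between the practice and test D
#' components across participants: the standard internal-consistency check
#' for an IAT administration.
#'
#' @param results A `dscore_results` object.
#' @param include_excluded Logical; include flagged participants.
#' @return A correlation in \[-1, 1\].
#' @export
practice_test_reliability <- function(results, include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"))
  keep <- displayed_rows(results, include_excluded)
  cols <- score_columns(results)
  dp <- results[[cols[["d_practice"]]]][keep]
  dt <- results[[cols[["d_test"]]]][keep]
  ok <- !is.na(dp) & !is.na(dt)
  if (sum(ok) < 3) {
    stop("practice-test reliability needs at least 3 participants with both ",
         "components defined", call. = FALSE)
  }
  if (stats::sd(dp[ok]) == 0 || stats::sd(dt[ok]) == 0) {
    stop("practice-test reliability undefined: zero variance in a component",
         call. = FALSE)
  }
  stats::cor(dp[ok], dt[ok])
}

DESCRIPTIVE_GROUPS <- c(
  "MappingA", "MappingB", "practice", "test",
  "practiceMappingA", "practiceMappingB", "testMappingA", "testMappingB"
)

#' Condition- and block-level descriptive statistics
#'
#' Mean response time and proportion of correct responses for the eight
#' standard groupings: each condition (all Mapping A trials pooled, all
#' Mapping B trials pooled), each block function (both practice blocks, both
#' test blocks) and each of the four individual blocks. The statistics are
#' computed on exactly the trials the D-score consumed: after slow-trial
#' removal and any lower-tail deletion, at post-inflation latencies, and
#' without participants flagged for exclusion (by default).
#'
#' @param results A `dscore_results` object from [score_dataset()].
#' @param include_excluded Logical; include flagged participants' trials.
#' @return A data frame with columns `grouping`, `n_trials`,
#'   `mean_latency` (ms) and `prop_correct`.
#' @export
compute_descriptives <- function(results, include_excluded = FALSE) {
  stopifnot(inherits(results, "dscore_results"))
  trials <- attr(results, "cleaned_trials")
  excluded_ids <- results$participant[results$excluded]
  if (!include_excluded && length(excluded_ids) > 0) {
    trials <- trials[!trials$participant %in% excluded_ids, , drop = FALSE]
  }
  member <- list(
    MappingA = trials$condition == "MappingA",
    MappingB = trials$condition == "MappingB",
    practice = trials$block_role %in% c("practice_A", "practice_B"),
    test = trials$block_role %in% c("test_A", "test_B"),
    practiceMappingA = trials$block_role == "practice_A",
    practiceMappingB = trials$block_role == "practice_B",
    testMappingA = trials$block_role == "test_A",
    testMappingB = trials$block_role == "test_B"
  )
  out <- do.call(rbind, lapply(DESCRIPTIVE_GROUPS, function(g) {
    sel <- member[[g]]
    data.frame(
      grouping = g,
      n_trials = sum(sel),
      mean_latency = mean_or_na(trials$latency_infl[sel]),
      prop_correct = prop_or_na(trials$correct[sel]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Textual report of a scored data set
#'
#' Prints the boxes of the interactive display as plain text: the six-number
#' summaries, the number of trials removed as slower than 10,000 ms ("None"
#' when there were none), the lower-tail count (or "Not expected for this D"
#' for D1/D3/D4), the practice-test reliability, the exclusion counts when
#' the corresponding cleaning options are on, and the condition/block
#' descriptive statistics.
#'
#' @param results A `dscore_results` object.
#' @param include_excluded Logical; include flagged participants in the
#'   summaries.
#' @param file Connection or path passed to [cat()]; defaults to stdout.
#' @return `results`, invisibly.
#' @export
dscore_report <- function(results, include_excluded = FALSE, file = "") {
  stopifnot(inherits(results, "dscore_results"))
  alg <- attr(results, "algorithm")
  cleaning <- attr(results, "cleaning")
  line <- function(...) cat(..., "\n", sep = "", file = file, append = TRUE)

  line("== D-score results (", alg$id, ", direction ",
       attr(results, "direction"), ") ==")
  line("Participants: ", nrow(results))
  line("")
  line("Summary (D-practice, D-test, D-score):")
  cat(paste(utils::capture.output(
    print(round(summarize_scores(results, include_excluded), 4))
  ), collapse = "\n"), "\n", file = file, append = TRUE)
  line("")

  n_slow <- attr(results, "removed_slow_total")
  line("Trials > 10,000 ms: ", if (n_slow == 0) "None" else n_slow)
  if (attr(results, "lower_tail_applicable")) {
    line("Trials < 400 ms: ", attr(results, "removed_lower_total"))
  } else {
    line("Trials < 400 ms: Not expected for this D")
  }

  rel <- tryCatch(practice_test_reliability(results, include_excluded),
                  error = function(e) NA_real_)
  line("Practice-Test reliability: ",
       if (is.na(rel)) "undefined" else round(rel, 4))

  if (cleaning$accuracy_cleaning) {
    line("Accuracy deletion (error % > ", cleaning$error_threshold, "%): ",
         sum(results$excluded_accuracy), " participant(s)")
  }
  if (cleaning$speed_cleaning) {
    line("Participants < 300 ms (> 10% fast trials): ",
         sum(results$excluded_speed), " participant(s)")
  }
  line("")
  line("Descriptive statistics (cleaned trials):")
  cat(paste(utils::capture.output(
    print(transform(compute_descriptives(results, include_excluded),
                    mean_latency = round(mean_latency, 1),
                    prop_correct = round(prop_correct, 4)))
  ), collapse = "\n"), "\n", file = file, append = TRUE)
  invisible(results)
}
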