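# Compact builders for trial tables used across the suite.

std_labels <- c(
  practice_A = "practiceMappingA", test_A = "testMappingA",
  practice_B = "practiceMappingB", test_B = "testMappingB"
)

block_df <- function(participant, block, latency, correct = 1) {
  data.frame(
    participant = participant, block = block, latency = latency,
    correct = rep_len(correct, length(latency)),
    stringsAsFactors = FALSE
  )
}

# One participant's four blocks from latency vectors (and optional accuracy
# vectors), using the standard labels.
participant_trials <- function(id, pa, ta, pb, tb,
                               cpa = 1, cta = 1, cpb = 1, ctb = 1) {
  rbind(
    block_df(id, std_labels[["practice_A"]], pa, cpa),
    block_df(id, std_labels[["test_A"]], ta, cta),
    block_df(id, std_labels[["practice_B"]], pb, cpb),
    block_df(id, std_labels[["test_B"]], tb, ctb)
  )
}

# A random micro-table for one participant: 2-8 trials per block, mixed
# errors, occasional slow outlier, latencies straddling the 400 ms mark.
random_micro_participant <- function(id) {
  do.call(rbind, lapply(names(std_labels), function(role) {
    n <- sample(2:8, 1)
    lat <- round(stats::runif(n, 250, 1500), 1)
    if (stats::runif(1) < 0.05) lat[1] <- round(stats::runif(1, 10500, 12000), 1)
    block_df(id, std_labels[[role]], lat, stats::rbinom(n, 1, 0.85))
  }))
}

random_micro_table <- function(n_participants, prefix = "p") {
  ids <- sprintf("%s%03d", prefix, seq_len(n_participants))
  do.call(rbind, lapply(ids, random_micro_participant))
}

# Minimal hand-built dscore_results (bypassing the pipeline) for summary,
# reliability and lookup tests where only the score vectors matter.
fake_results <- function(d_practice, d_test, excluded = FALSE,
                         algorithm = "D3") {
  n <- length(d_practice)
  alg <- algorithm_spec(algorithm)
  df <- data.frame(
    participant = sprintf("p%05d", seq_len(n)),
    excluded = rep_len(excluded, n),
    stringsAsFactors = FALSE
  )
  df[[paste0("d_practice.", alg$number)]] <- d_practice
  df[[paste0("d_test.", alg$number)]] <- d_test
  df[[paste0("dscore.", alg$number)]] <- (d_practice + d_test) / 2
  structure(df, algorithm = alg, direction = "B-A",
            class = c("dscore_results", "data.frame"))
}

# A small well-behaved scored sample for reporting/visualization tests.
scored_fixture <- function(n = 8, delta = 100, seed = 11, algorithm = "D3",
                           cleaning = cleaning_config()) {
  sim <- generate_dataset(simulation_config(
    n_participants = n, effect_delta = delta, seed = seed
  ))
  score_dataset(validate_trials(sim$trials), algorithm, cleaning = cleaning)
}
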