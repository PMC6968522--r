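make_single <- function(latencies, correct = 1) {
  # one participant, latencies split evenly-ish over the four blocks
  n <- length(latencies)
  idx <- rep(1:4, length.out = n)
  validate_trials(rbind(
    block_df("s1", std_labels[["practice_A"]], latencies[idx == 1],
             rep_len(correct, n)[idx == 1]),
    block_df("s1", std_labels[["test_A"]], latencies[idx == 2],
             rep_len(correct, n)[idx == 2]),
    block_df("s1", std_labels[["practice_B"]], latencies[idx == 3],
             rep_len(correct, n)[idx == 3]),
    block_df("s1", std_labels[["test_B"]], latencies[idx == 4],
             rep_len(correct, n)[idx == 4])
  ))
}

test_that("slow-trial removal uses a strict 10,000 ms cutoff and is idempotent", {
  tr <- make_single(c(250, 399, 400, 5000, 12000, 10000, 800, 900))
  out <- remove_slow_trials(tr)
  expect_equal(unname(out$counts), 1)
  expect_setequal(out$trials$latency, c(250, 399, 400, 5000, 10000, 800, 900))

  again <- remove_slow_trials(out$trials)
  expect_equal(unname(again$counts), 0)
  expect_equal(again$trials$latency, out$trials$latency)
})

test_that("lower-tail deletion applies only to D2/D5/D6, strictly below 400 ms", {
  tr <- make_single(c(250, 399, 400, 5000, 800, 900, 1000, 1100))
  for (a in c("D2", "D5", "D6")) {
    out <- remove_lower_tail(tr, a)
    expect_true(out$applicable)
    expect_equal(unname(out$counts), 2)
    expect_false(any(out$trials$latency < 400))
    expect_true(400 %in% out$trials$latency)  # boundary trial retained
  }
  for (a in c("D1", "D3", "D4")) {
    out <- remove_lower_tail(tr, a)
    expect_false(out$applicable)
    expect_true(is.na(out$counts))
    expect_equal(nrow(out$trials), nrow(tr))
  }
})

test_that("fast-trial counts are strict and nested: num_300 <= num_400 <= n", {
  tr <- make_single(c(250, 299, 300, 800, 399, 400, 900, 1000))
  expect_equal(unname(count_fast_trials(tr, 300)), 2)
  expect_equal(unname(count_fast_trials(tr, 400)), 4)

  set.seed(404)
  big <- validate_trials(random_micro_table(20))
  n300 <- count_fast_trials(big, 300)
  n400 <- count_fast_trials(big, 400)
  ntot <- table(big$participant)[names(n300)]
  expect_true(all(n300 <= n400))
  expect_true(all(n400 <= ntot))
})

test_that("accuracy flag fires strictly above the threshold, per condition", {
  # 6 errors in 20 Mapping A trials (30%) vs a clean Mapping B
  correct_a <- rep(c(0, 1), c(6, 14))
  tr <- validate_trials(participant_trials(
    "s1",
    pa = seq(500, 590, by = 10), ta = seq(600, 690, by = 10),
    pb = seq(700, 790, by = 10), tb = seq(800, 890, by = 10),
    cpa = correct_a[1:10], cta = correct_a[11:20]
  ))
  cfg <- cleaning_config(accuracy_cleaning = TRUE)
  expect_true(flag_inaccurate_participants(tr, cfg)[["s1"]])

  # exactly 25% in both conditions is NOT flagged ("exceeding" is strict)
  correct_q <- rep(c(0, 1), c(5, 15))
  tr25 <- validate_trials(participant_trials(
    "s1",
    pa = seq(500, 590, by = 10), ta = seq(600, 690, by = 10),
    pb = seq(700, 790, by = 10), tb = seq(800, 890, by = 10),
    cpa = correct_q[1:10], cta = correct_q[11:20],
    cpb = correct_q[1:10], ctb = correct_q[11:20]
  ))
  expect_false(flag_inaccurate_participants(tr25, cfg)[["s1"]])

  # all correct, or cleaning off: never flagged
  clean <- make_single(seq(500, 1200, length.out = 8))
  expect_false(flag_inaccurate_participants(clean, cfg)[["s1"]])
  expect_false(flag_inaccurate_participants(tr, cleaning_config())[["s1"]])
})

test_that("speed flag fires strictly above 10% of trials under 300 ms", {
  lat_13 <- c(rep(250, 13), seq(500, 500 + 106, by = 1))  # 13 of 120 fast
  tr13 <- make_single(lat_13)
  cfg <- cleaning_config(speed_cleaning = TRUE)
  expect_true(flag_fast_participants(tr13, cfg)[["s1"]])

  lat_12 <- c(rep(250, 12), seq(500, 500 + 107, by = 1))  # exactly 10%
  expect_false(flag_fast_participants(make_single(lat_12), cfg)[["s1"]])

  expect_false(flag_fast_participants(make_single(lat_13),
                                      cleaning_config())[["s1"]])
  expect_false(flag_fast_participants(
    make_single(seq(500, 1200, length.out = 8)), cfg)[["s1"]])
})

test_that("exclusion flags keep every participant in the results table", {
  # engineer one participant over the accuracy threshold
  bad <- participant_trials(
    "bad",
    pa = seq(500, 590, by = 10), ta = seq(600, 690, by = 10),
    pb = seq(700, 790, by = 10), tb = seq(800, 890, by = 10),
    cpa = rep(c(0, 1), c(6, 4)), cta = rep(c(0, 1), c(3, 7))
  )
  good <- participant_trials("good", c(500, 600), c(700, 800),
                             c(900, 1000), c(1100, 1200))
  res <- score_dataset(
    validate_trials(rbind(bad, good)), "D3",
    cleaning = cleaning_config(accuracy_cleaning = TRUE)
  )
  expect_equal(nrow(res), 2)
  expect_true(res$excluded[res$participant == "bad"])
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, f)
  expect_equal(length(readLines(f)) - 1, 2)  # both rows written
})
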