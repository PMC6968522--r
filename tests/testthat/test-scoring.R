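test_that("algorithm table maps ids to inflation strategy and lower tail", {
  expect_equal(algorithm_spec("D1")$error_inflation, "builtin")
  expect_false(algorithm_spec("D1")$lower_tail_deletion)
  expect_equal(algorithm_spec(2)$error_inflation, "builtin")
  expect_true(algorithm_spec("d2")$lower_tail_deletion)
  expect_equal(algorithm_spec("D3")$error_inflation, "mean_plus_2sd")
  expect_equal(algorithm_spec("D4")$error_inflation, "mean_plus_600")
  expect_true(algorithm_spec("D5")$lower_tail_deletion)
  expect_true(algorithm_spec("D6")$lower_tail_deletion)
  expect_error(algorithm_spec("D7"), "unknown algorithm")
})

test_that("error inflation matches the hand-computed fixtures", {
  # correct latencies {500, 700}: mean 600, sample SD 141.4214
  lat <- c(500, 700, 650)
  cor <- c(1, 1, 0)
  expect_equal(inflate_errors(lat, cor, "mean_plus_600"),
               c(500, 700, 1200))
  expect_equal(inflate_errors(lat, cor, "mean_plus_2sd"),
               c(500, 700, 600 + 2 * sd(c(500, 700))))
  expect_equal(inflate_errors(lat, cor, "mean_plus_2sd")[3], 882.842712,
               tolerance = 1e-6)
  # builtin never alters anything
  expect_identical(inflate_errors(lat, cor, "builtin"), lat)
  # correct trials never altered by any strategy
  expect_equal(inflate_errors(lat, cor, "mean_plus_600")[1:2], lat[1:2])
})

test_that("ex-post inflation is undefined without enough correct trials", {
  expect_error(inflate_errors(c(500, 600), c(0, 0), "mean_plus_600"),
               class = "iatdscore_undefined")
  expect_error(inflate_errors(c(500, 600), c(1, 0), "mean_plus_2sd"),
               class = "iatdscore_undefined")
  # one correct trial is enough for the fixed 600 ms penalty
  expect_equal(inflate_errors(c(500, 600), c(1, 0), "mean_plus_600"),
               c(500, 1100))
})

test_that("pooled SD is the sample SD of the concatenation", {
  expect_equal(pooled_sd(c(500, 700), c(700, 900)), sqrt(80000 / 3))
  expect_equal(pooled_sd(c(500, 700), c(700, 900)), 163.2993,
               tolerance = 1e-6)
  expect_identical(pooled_sd(c(500, 700), c(700, 900)),
                   pooled_sd(c(700, 900), c(500, 700)))
  expect_error(pooled_sd(c(700, 700), c(700, 700)),
               class = "iatdscore_undefined")
  expect_error(pooled_sd(numeric(0), 700), class = "iatdscore_undefined")
})

test_that("d_component matches the hand oracle and flips with direction", {
  d <- d_component(c(500, 700), c(700, 900))
  expect_equal(d, 200 / sqrt(80000 / 3))
  expect_equal(d, 1.224745, tolerance = 1e-6)
  expect_identical(d_component(c(500, 700), c(700, 900), "A-B"), -d)
  expect_equal(d_component(c(500, 700), c(500, 700)), 0)
  expect_error(d_component(numeric(0), c(500, 700)),
               class = "iatdscore_undefined")
})

test_that("score_participant averages the two components", {
  tr <- validate_trials(participant_trials(
    "s1", pa = c(500, 700), pb = c(700, 900),
    ta = c(600, 800), tb = c(650, 850)
  ))
  sc <- score_participant(tr, "D1")
  expect_equal(sc$d_practice, d_component(c(500, 700), c(700, 900)))
  expect_equal(sc$d_test, d_component(c(600, 800), c(650, 850)))
  expect_equal(sc$dscore, (sc$d_practice + sc$d_test) / 2)
  expect_true(is.na(sc$reason))

  # identical latency distributions in every block: score is exactly 0
  same <- validate_trials(participant_trials(
    "s1", pa = c(500, 700), ta = c(500, 700),
    pb = c(500, 700), tb = c(500, 700)
  ))
  for (a in paste0("D", 1:6)) {
    expect_equal(score_participant(same, a)$dscore, 0)
  }
})

test_that("undefined components surface as NA with a reason, not an abort", {
  # practice_B all errors: ex-post inflation has no correct-trial mean
  tr <- validate_trials(participant_trials(
    "s1", pa = c(500, 700), ta = c(600, 800),
    pb = c(700, 900), tb = c(650, 850), cpb = 0
  ))
  sc <- score_participant(tr, "D3")
  expect_true(is.na(sc$d_practice))
  expect_false(is.na(sc$d_test))
  expect_true(is.na(sc$dscore))
  expect_match(sc$reason, "no_correct_trials")
  # builtin is indifferent to the accuracy pattern
  expect_false(is.na(score_participant(tr, "D1")$dscore))

  # scoring a batch keeps the broken participant as an NA row
  good <- participant_trials("s2", c(500, 700), c(600, 800),
                             c(700, 900), c(650, 850))
  res <- score_dataset(validate_trials(rbind(
    participant_trials("s1", c(500, 700), c(600, 800),
                       c(700, 900), c(650, 850), cpb = 0),
    good
  )), "D3")
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$dscore.3[1]))
  expect_false(is.na(res$dscore.3[2]))
})

test_that("score_dataset is deterministic and order-free within blocks", {
  set.seed(99)
  df <- random_micro_table(12)
  tr <- validate_trials(df)
  res1 <- score_dataset(tr, "D5")
  res2 <- score_dataset(tr, "D5")
  expect_identical(as.data.frame(res1), as.data.frame(res2))

  # permute rows within each participant x block
  perm <- df[order(df$participant, df$block, runif(nrow(df))), ]
  res3 <- score_dataset(validate_trials(perm), "D5")
  res3 <- res3[match(res1$participant, res3$participant), ]
  expect_equal(res1$dscore.5, res3$dscore.5)
  expect_equal(res1$mean.tot, res3$mean.tot)
})

test_that("effect-size bands follow the 0.15 / 0.35 / 0.65 cutoffs", {
  eff <- classify_effect_size(c(0.70, -0.40, 0.0, 0.15, -0.649, 0.349, NA))
  expect_equal(as.character(eff$magnitude),
               c("strong", "moderate", "negligible", "slight", "moderate",
                 "slight", NA))
  expect_equal(eff$sign,
               c("positive", "negative", "zero", "positive", "negative",
                 "positive", NA))
})

test_that("equal-size blocks bound the component by 2*sqrt(n/(n-1))", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    a <- runif(n, 300, 2000)
    b <- runif(n, 300, 2000)
    d <- tryCatch(d_component(a, b), iatdscore_undefined = function(e) 0)
    expect_lte(abs(d), 2 * sqrt(n / (n - 1)) + 1e-12)
  }
})
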