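# Naive brute-force D-score oracle: a straight, loop-level transcription of
# the algorithm table (error inflation x lower-tail deletion) and the three
# defining equations, written independently of the package's scoring path.
# It consumes a raw data frame (participant, block, latency, correct) for a
# single participant and applies every step itself.

naive_alg_table <- list(
  D1 = list(infl = "builtin", tail = FALSE),
  D2 = list(infl = "builtin", tail = TRUE),
  D3 = list(infl = "2sd",     tail = FALSE),
  D4 = list(infl = "600",     tail = FALSE),
  D5 = list(infl = "2sd",     tail = TRUE),
  D6 = list(infl = "600",     tail = TRUE)
)

naive_role_of_label <- c(
  practiceMappingA = "practice_A", testMappingA = "test_A",
  practiceMappingB = "practice_B", testMappingB = "test_B"
)

# Treated (post-inflation) latencies of one block; NULL if the block is
# empty, NA if the inflation is undefined for it.
naive_treat_block <- function(latency, correct, infl) {
  if (length(latency) == 0) return(NULL)
  if (infl == "builtin" || all(correct == 1)) return(latency)
  ok <- latency[correct == 1]
  if (length(ok) == 0) return(NA_real_)
  if (infl == "2sd") {
    if (length(ok) < 2) return(NA_real_)
    pen <- 2 * stats::sd(ok)
  } else {
    pen <- 600
  }
  out <- latency
  for (i in seq_along(out)) {
    if (correct[i] == 0) out[i] <- mean(ok) + pen
  }
  out
}

naive_component <- function(lat_A, lat_B) {
  if (is.null(lat_A) || is.null(lat_B)) return(NA_real_)
  if (anyNA(lat_A) || anyNA(lat_B)) return(NA_real_)
  pooled <- c(lat_A, lat_B)
  if (length(pooled) < 2) return(NA_real_)
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) return(NA_real_)
  (mean(lat_B) - mean(lat_A)) / s
}

naive_dscore <- function(df, algorithm, direction = "B-A") {
  spec <- naive_alg_table[[algorithm]]
  df <- df[df$latency <= 10000, , drop = FALSE]
  if (spec$tail) df <- df[df$latency >= 400, , drop = FALSE]
  role <- naive_role_of_label[df$block]
  treated <- function(r) {
    sel <- which(role == r)
    naive_treat_block(df$latency[sel], df$correct[sel], spec$infl)
  }
  d_prac <- naive_component(treated("practice_A"), treated("practice_B"))
  d_test <- naive_component(treated("test_A"), treated("test_B"))
  if (direction == "A-B") {
    d_prac <- -d_prac
    d_test <- -d_test
  }
  list(d_practice = d_prac, d_test = d_test, dscore = (d_prac + d_test) / 2)
}
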