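---
title: "Scoring the Implicit Association Test: models, cleaning rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the Implicit Association Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatdscore)
```

## The measurement problem

The Implicit Association Test records, trial by trial, how quickly and how
accurately a respondent sorts stimuli under two key-mapping conditions: in
Mapping A one pair of concepts shares a response key, in Mapping B the
pairing is switched. Each condition is administered as a practice block and
a test block, so an analysis-ready data set contains four critical blocks
per participant (pure practice blocks, which involve only one stimulus
dimension, are removed beforehand). The behavioral signature of an
automatic association is a latency difference between the two conditions,
and the conventional effect measure is the D-score: an individually
standardized mean difference.

## The D-score family

For participant $i$, let $M^{A}_{p}$, $M^{B}_{p}$ be the mean
(post-error-treatment) latencies of the Mapping A and Mapping B *practice*
blocks and $M^{A}_{t}$, $M^{B}_{t}$ the same for the *test* blocks. Then

$$
D_{\text{practice}} = \frac{M^{B}_{p} - M^{A}_{p}}{SD_{p}}, \qquad
D_{\text{test}} = \frac{M^{B}_{t} - M^{A}_{t}}{SD_{t}}, \qquad
D = \frac{D_{\text{practice}} + D_{\text{test}}}{2},
$$

where $SD_p$ (resp. $SD_t$) is the sample standard deviation of the pooled
trials of the two practice (resp. test) blocks. The subtraction order is
arbitrary; the package default is B − A, and reversing it — either via the
`direction` argument or by swapping the Mapping A/B role labels — negates
every score exactly.

The six algorithms D1–D6 differ in two treatments applied *before* the
means and SDs are taken:

* **Error inflation.** With a built-in correction procedure (D1/D2) the
  respondent had to correct each error before continuing, so the recorded
  latency already contains the penalty and is used as is. Without it
  (D3–D6), each error latency is replaced ex post by the mean correct-trial
  latency of the block in which the error occurred plus a penalty: twice
  the block SD (D3/D5) or a fixed 600 ms (D4/D6).
* **Lower tail.** D2/D5/D6 delete trials faster than 400 ms; D1/D3/D4 keep
  them (diagnostic counts are reported either way).

All algorithms share the removal of trials slower than 10,000 ms.

## Cleaning order and boundary conventions

The order in which filters and flags interact is not dictated by the
scoring equations, so the package fixes and documents one:

1. remove trials with latency > 10,000 ms;
2. on the remaining trials, count trials < 300 ms and < 400 ms and evaluate
   the participant-level flags — *speed* (more than 10% of trials under
   300 ms) and *accuracy* (error percentage above the threshold, default
   25%, in at least one condition, trials pooled over the condition's two
   blocks);
3. delete trials < 400 ms when the algorithm calls for it;
4. inflate error latencies and score.

Evaluating the flags after the slow-trial removal but before the lower-tail
deletion keeps them identical across algorithms and keeps the `num.400`
diagnostic well defined for algorithms that do not delete. Every threshold
is a strict inequality as conventionally worded ("higher than 10,000 ms",
"faster than 300 ms", "more than 10%", "exceeding 25%"): a trial at exactly
10,000 ms or 400 ms is retained, a participant at exactly the 25% or 10%
mark is not excluded. Exclusion flags never remove rows from the results
table — they only gate the displayed summaries, the reliability index and
the descriptive statistics.

Participants whose score cannot be computed (a block emptied by filtering,
an ex-post strategy with no correct trial in a block — or a single one, for
the 2 SD penalty — or zero pooled variance) are retained with missing
components and a machine-readable reason, so one degenerate respondent
never aborts a batch.

## Numerical and interface choices

Several quantities are conventionally under-specified; the package fixes
them as follows, once:

* **SD for the 2 SD penalty**: computed on the block's *correct* trials,
  the same trials that define the mean being penalized.
* **Pooled SD**: computed on *post-inflation* latencies (error trials enter
  at their replaced values, built-in latencies as recorded), because the
  treatments are defined as preceding the score and the pooled trials of
  both blocks include error trials. `mean.tot` and the descriptive
  statistics use the same post-inflation latencies, so every reported
  latency quantity describes the data the score actually consumed.
* **Sample SD** (n − 1 denominator) everywhere.
* **Quartiles** in the six-number summaries: linear interpolation between
  order statistics (R's default quantile type 7).
* **Reliability**: Pearson product-moment correlation between
  $D_{\text{practice}}$ and $D_{\text{test}}$ across participants.
* **`cond_ord`** (presentation order of the conditions): derived from the
  condition of each participant's first trial in file order — row order is
  the only presentation-order signal the input schema carries.
* **Built-in-corrected data and the lower tail**: D2's < 400 ms deletion is
  applied to the latency column as given (i.e., to the already-inflated
  latencies), since those are the only latencies the file contains.
* **Plots**: the density display uses a Gaussian kernel with R's default
  plug-in bandwidth; the histogram default is 30 bins; reference lines sit
  at the ±0.15/±0.35/±0.65 effect bands. Both defaults are deterministic
  and documented rather than inherited from any interactive tool.

## What the synthetic generator emulates

`generate_dataset()` draws latencies from an ex-Gaussian distribution — a
Gaussian of mean `mu` and SD `sigma` convolved with an exponential of mean
`tau` — the standard phenomenological model for response times, with
defaults `mu = 600`, `sigma = 100`, `tau = 150` ms (typical magnitudes for
speeded categorization; conventions of this package, not estimates from any
particular study). Block sizes default to 20 trials per practice block and
40 per test block, the common administration design. Errors are Bernoulli
per condition at a default rate of 0.05, a typical IAT error rate. A
condition effect of `effect_delta` ms is added to every Mapping B latency,
so a positive delta slows Mapping B and produces a positive B − A D-score.
Under `builtin_correction`, error latencies are additionally inflated by
`correction_penalty_ms` (default 400 ms, a plausible correction time;
no published convention exists). Optional contamination replaces trials
with uniform draws below 300 ms or above 10,000 ms so that the cleaning
rules can be exercised with known ground truth, which is returned alongside
the trials and written as a JSON sidecar by `write_simulation()`.

The generator reproduces the *format* and the first-order structure of IAT
data, not its full phenomenology: no sequential dependencies between
trials, no speed–accuracy trade-off (accuracy is independent of the drawn
latency), no participant-level heterogeneity in error rates or in the
effect itself, and identical ex-Gaussian parameters for every block.
Passing recovery tests on this generator therefore demonstrates that the
scoring arithmetic and cleaning rules behave as specified — not that the
D-score is unbiased for any particular empirical population.

## Validation design

The test suite checks the scoring core against an independently written
brute-force oracle (a plain-loop transcription of the algorithm table and
the three defining equations) on 500 random micro-tables of 2–8 trials per
block with mixed errors, for all six algorithms and both directions, at a
10⁻¹² tolerance; hand-computed fixtures anchor the pooled SD
(163.299 for {500, 700} ∪ {700, 900}), the standardized difference
(1.2247) and both inflation penalties (1200 and 882.84 for an error in a
block with correct latencies {500, 700}). Property tests assert exact
antisymmetry under label swap, shift invariance of all six algorithms, and
scale invariance of D1/D3/D5 but not of D4/D6 (whose fixed 600 ms penalty
deliberately breaks it). Simulation checks use 500 participants for the
null condition (mean D within 3 standard errors of zero, skewness within
sampling bounds) and 200 participants per point for a 0/80/160 ms
effect-recovery sweep — sizes chosen to make sampling error small relative
to the assertions while keeping the default test run fast.

## Known limitations

* Only the standard seven-block IAT reduced to its four critical blocks is
  supported: no Brief-IAT, single-category variants, or multi-session
  designs, and no split-half or test–retest reliability.
* Latencies must arrive in milliseconds; there is no unit autodetection,
  because silently rescaling would corrupt every fixed threshold.
* Input files must be comma-separated; the four required columns may appear
  in any order and extra columns are ignored, but other separators are
  rejected rather than guessed.
* The accuracy flag is computed from the `correct` codes as given; for
  built-in-correction data, where errors were corrected on-line, the error
  percentage still refers to the first response being wrong.
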