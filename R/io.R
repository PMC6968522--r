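#' @keywords internal
"_PACKAGE"

# Canonical block roles and the condition each belongs to.
BLOCK_ROLES <- c("practice_A", "test_A", "practice_B", "test_B")
ROLE_CONDITION <- c(
  practice_A = "MappingA", test_A = "MappingA",
  practice_B = "MappingB", test_B = "MappingB"
)
REQUIRED_COLUMNS <- c("participant", "block", "latency", "correct")

#' Read a trial-level IAT CSV file
#'
#' Reads a comma-separated file holding one row per IAT trial. The file must
#' contain the columns `participant`, `block`, `latency` (milliseconds) and
#' `correct` (0 = incorrect, 1 = correct) in any order; extra columns are
#' ignored. Only the four critical blocks (practice/test x Mapping A/B) should
#' be present -- pure practice blocks must be removed before reading.
#'
#' @param path Path to a CSV file with a header row and comma separator.
#' @return A data frame with columns `participant`, `block`, `latency`,
#'   `correct`, one row per trial, in file order.
#' @seealso [validate_trials()] to annotate block roles, [write_template()]
#'   for an example of the expected layout.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write_template(tf)
#' head(read_trials_csv(tf))
read_trials_csv <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "required column(s) not found: ", paste(missing_cols, collapse = ", "),
      ". The file must be comma-separated with columns ",
      paste(REQUIRED_COLUMNS, collapse = ", "), ".",
      call. = FALSE
    )
  }
  raw <- raw[REQUIRED_COLUMNS]
  for (col in c("latency", "correct")) {
    if (!is.numeric(raw[[col]])) {
      suppressWarnings(num <- as.numeric(raw[[col]]))
      bad <- which(is.na(num) & !is.na(raw[[col]]))
      if (length(bad) > 0) {
        stop(
          "non-numeric values in column '", col, "' at row(s): ",
          paste(utils::head(bad, 10), collapse = ", "),
          call. = FALSE
        )
      }
      raw[[col]] <- num
    }
  }
  raw$participant <- as.character(raw$participant)
  raw$block <- as.character(raw$block)
  raw
}

#' Define the mapping from raw block labels to block roles
#'
#' An IAT data set labels its four critical blocks with free-text strings.
#' Scoring needs to know which label plays which role: the practice and test
#' block of the Mapping A condition and the practice and test block of the
#' Mapping B condition. Swapping the A and B assignments reverses the sign of
#' every D-score (the subtraction order of the block means flips).
#'
#' @param practice_A,test_A,practice_B,test_B Raw block labels (character
#'   scalars), pairwise distinct.
#' @return A named character vector of length 4 with names
#'   `practice_A`, `test_A`, `practice_B`, `test_B`.
#' @export
#' @examples
#' block_roles("practiceMappingA", "testMappingA",
#'             "practiceMappingB", "testMappingB")
block_roles <- function(practice_A, test_A, practice_B, test_B) {
  roles <- c(
    practice_A = as.character(practice_A), test_A = as.character(test_A),
    practice_B = as.character(practice_B), test_B = as.character(test_B)
  )
  if (anyDuplicated(roles)) {
    stop("the four block labels must be pairwise distinct", call. = FALSE)
  }
  roles
}

# Guess the role map when labels follow the (practice|test)Mapping(A|B)
# convention used by the template and the simulator; NULL when ambiguous.
guess_block_roles <- function(labels) {
  labels <- unique(labels)
  if (length(labels) != 4) return(NULL)
  pat <- c(
    practice_A = "^practice.*a$", test_A = "^test.*a$",
    practice_B = "^practice.*b$", test_B = "^test.*b$"
  )
  hit <- vapply(pat, function(p) {
    m <- labels[grepl(p, tolower(labels))]
    if (length(m) == 1) m else NA_character_
  }, character(1))
  if (anyNA(hit) || anyDuplicated(hit)) return(NULL)
  hit
}

#' Validate raw trials and annotate block roles and conditions
#'
#' Checks the schema-level invariants of a trial table (accuracy coded 0/1,
#' finite non-negative latencies, exactly four distinct block labels, every
#' participant observed in all four blocks) and annotates each trial with its
#' block role and mapping condition. The returned table is the single currency
#' consumed by every downstream operation.
#'
#' @param raw A data frame as returned by [read_trials_csv()].
#' @param roles A role map from [block_roles()]. When `NULL`, the labels are
#'   matched against the `practice`/`test` x `...A`/`...B` naming convention;
#'   an error is raised if they cannot be matched unambiguously.
#' @param builtin_corrected Logical; `TRUE` when the administration procedure
#'   used a built-in error correction, so latencies already include the time
#'   needed to correct the response (algorithms D1/D2 assume this).
#' @return An object of class `iat_trials`: the input data frame plus columns
#'   `block_role` and `condition`, with attributes `roles` and
#'   `builtin_corrected`.
#' @export
validate_trials <- function(raw, roles = NULL, builtin_corrected = FALSE) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("required column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_correct <- setdiff(unique(raw$correct), c(0, 1))
  if (length(bad_correct) > 0) {
    stop(
      "'correct' must contain only 0 (incorrect) and 1 (correct); found: ",
      paste(bad_correct, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!is.finite(raw$latency)) || any(raw$latency < 0)) {
    stop("'latency' must be finite and non-negative milliseconds",
         call. = FALSE)
  }
  labels <- unique(raw$block)
  if (length(labels) > 4) {
    stop(
      length(labels), " distinct block labels found; only the four critical ",
      "blocks are allowed. Pure practice blocks must be removed before scoring.",
      call. = FALSE
    )
  }
  if (length(labels) < 4) {
    stop("fewer than four distinct block labels found (",
         paste(labels, collapse = ", "),
         "); the four critical blocks must be uniquely labeled",
         call. = FALSE)
  }
  if (is.null(roles)) {
    roles <- guess_block_roles(labels)
    if (is.null(roles)) {
      stop(
        "block labels (", paste(labels, collapse = ", "), ") do not follow ",
        "the practice/test MappingA/MappingB convention; supply `roles` via ",
        "block_roles()",
        call. = FALSE
      )
    }
  }
  if (!setequal(names(roles), BLOCK_ROLES) || anyDuplicated(roles)) {
    stop("`roles` must assign four distinct labels to the roles ",
         paste(BLOCK_ROLES, collapse = ", "), call. = FALSE)
  }
  if (!setequal(roles, labels)) {
    stop("role labels (", paste(roles, collapse = ", "),
         ") must cover exactly the labels present in the data (",
         paste(labels, collapse = ", "), ")", call. = FALSE)
  }

  role_of <- stats::setNames(names(roles), roles)
  out <- raw
  out$participant <- as.character(out$participant)
  out$correct <- as.integer(out$correct)
  out$block_role <- unname(role_of[out$block])
  out$condition <- unname(ROLE_CONDITION[out$block_role])

  by_part <- tapply(out$block_role, out$participant,
                    function(r) length(unique(r)))
  incomplete <- names(by_part)[by_part < 4]
  if (length(incomplete) > 0) {
    stop(
      "participant(s) missing one or more of the four blocks: ",
      paste(incomplete, collapse = ", "),
      ". All four blocks are required to compute a D-score.",
      call. = FALSE
    )
  }

  structure(
    out,
    roles = roles,
    builtin_corrected = isTRUE(builtin_corrected),
    class = c("iat_trials", "data.frame")
  )
}

# Filters return plain data frames; this re-attaches the table metadata.
keep_trial_attrs <- function(new, old) {
  structure(
    new,
    roles = attr(old, "roles"),
    builtin_corrected = attr(old, "builtin_corrected"),
    class = c("iat_trials", "data.frame")
  )
}

#' Write a CSV template for trial-level IAT data
#'
#' Writes a small illustrative file in the expected input layout: header
#' `participant,block,latency,correct` and a few rows covering all four
#' critical blocks.
#'
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_template <- function(path) {
  blocks <- c("practiceMappingA", "testMappingA",
              "practiceMappingB", "testMappingB")
  template <- data.frame(
    participant = rep("subj01", 8),
    block = rep(blocks, each = 2),
    latency = c(642, 871, 705, 590, 933, 1104, 851, 766),
    correct = c(1, 1, 1, 0, 1, 1, 0, 1)
  )
  utils::write.csv(template, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# The 21 result-file column names, in print order, for algorithm number `n`.
results_columns <- function(n) {
  c(
    "participant", "n_trial", "slow10000", "num.300", "num.400", "mean.tot",
    "p_correct_block.practice.MappingA", "p_correct_block.practice.MappingB",
    "p_correct_block.test.MappingA", "p_correct_block.test.MappingB",
    "p_correct_bpool.practice", "p_correct_bpool.test",
    "prop_correct_cond_MappingA", "prop_correct_cond_MappingB",
    "p_correct_tot",
    paste0("d_practice.", n), paste0("d_test.", n), paste0("dscore.", n),
    "cond_ord", "LegendMappingA", "LegendMappingB"
  )
}

#' Default file name for a results CSV
#'
#' @param algorithm Algorithm id (`"D1"`..`"D6"`), number, or spec.
#' @return A file name such as `"ShinyAPPDscore3.csv"`.
#' @export
default_results_filename <- function(algorithm) {
  paste0("ShinyAPPDscore", algorithm_spec(algorithm)$number, ".csv")
}

#' Write scored results to the standard CSV layout
#'
#' Writes one row per participant -- including participants flagged for
#' exclusion by the cleaning rules -- with the 21 standard columns, in order:
#' ID, trial-count diagnostics, proportion-correct fields per block, block
#' pool and condition, the D components and D-score (columns numbered after
#' the algorithm, e.g. `dscore.3` for D3), the condition presentation order,
#' and the raw block labels behind each mapping.
#'
#' @param results A `dscore_results` object from [score_dataset()].
#' @param path Destination file path; defaults to
#'   [default_results_filename()] in the working directory.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path = NULL) {
  stopifnot(inherits(results, "dscore_results"))
  if (nrow(results) == 0) stop("`results` is empty", call. = FALSE)
  alg <- attr(results, "algorithm")
  if (is.null(path)) path <- default_results_filename(alg)
  cols <- results_columns(alg$number)
  utils::write.csv(as.data.frame(results)[cols], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
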