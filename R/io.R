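TRIAL_COLS <- c("child_id", "age", "experiment", "condition", "object_id",
                "correct")

#' Validate a trial table
#'
#' Checks the trial schema and its invariants, reporting offending row
#' numbers: ages in `[2, 5)`, binary responses, known experiment and
#' condition labels, no familiar object on discourse-novelty (exp2) rows and
#' an explicit alignment condition on every combined-design (exp3) row.
#'
#' @param trials Data frame with columns `child_id`, `age`, `experiment`,
#'   `condition`, `object_id`, `correct`.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("trial table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  trials <- trials[, TRIAL_COLS]
  if (nrow(trials) == 0) return(trials)
  bad <- function(rows, what) {
    if (length(rows) > 0) {
      abort_schema(paste0(what, " (row ",
                          paste(head(rows, 5), collapse = ", "),
                          if (length(rows) > 5) ", ..." else "", ")"))
    }
  }
  bad(which(!is.finite(trials$age) | trials$age < 2 | trials$age >= 5),
      "age must lie in [2, 5)")
  bad(which(!trials$correct %in% c(0, 1)), "correct must be 0 or 1")
  bad(which(!trials$experiment %in% c("exp1", "exp2", "exp3")),
      "experiment must be exp1, exp2 or exp3")
  bad(which(!trials$condition %in% c("congruent", "incongruent", "none")),
      "condition must be congruent, incongruent or none")
  bad(which(trials$experiment == "exp2" & !is.na(trials$object_id)),
      "exp2 rows carry no familiar object")
  bad(which(trials$experiment == "exp3" & trials$condition == "none"),
      "exp3 rows need a congruent/incongruent condition")
  bad(which(trials$experiment != "exp3" & trials$condition != "none"),
      "exp1/exp2 rows have condition 'none'")
  trials$correct <- as.integer(trials$correct)
  trials
}

#' Read and write trial tables
#'
#' CSV with a mandatory header (`child_id, age, experiment, condition,
#' object_id, correct`), comma-separated, UTF-8, dot decimal. Ages are
#' written with full precision so a write/read round trip reproduces the
#' table exactly.
#'
#' @param path File path.
#' @return `read_trials()`: the validated trial tibble.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort_schema(paste0("no such file: ", path))
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      age = readr::col_double(),
      experiment = readr::col_character(),
      condition = readr::col_character(),
      object_id = readr::col_character(),
      correct = readr::col_double()
    )
  )
  validate_trials(trials)
}

#' @rdname read_trials
#' @param trials Trial tibble.
#' @return `write_trials()`: the input, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  readr::write_csv(trials, path)
  invisible(trials)
}
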