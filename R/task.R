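#' Generate a task schedule
#'
#' A session presents four stimuli, one per condition (Go-to-Win, NoGo-to-Win,
#' Go-to-Avoid-Loss, NoGo-to-Avoid-Loss), for \code{n_per_condition} trials
#' each in fully randomized order.  Feedback validity is pre-drawn per trial:
#' with probability \code{feedback_validity} (0.8 in the task) the better
#' outcome for the chosen action is delivered.
#'
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param n_per_condition Trials per stimulus (default 36, i.e. 144 in all).
#' @param feedback_validity Probability that feedback is valid (default 0.8).
#' @return Tibble with columns \code{trial_index}, \code{stimulus_id},
#'   \code{condition}, \code{correct_action}, \code{validity_draw}.
#' @examples
#' sched <- gng_schedule(seed = 1)
#' table(sched$condition)
#' @export
gng_schedule <- function(seed, n_per_condition = 36, feedback_validity = 0.8) {
  if (n_per_condition < 1) abort("n_per_condition must be >= 1")
  n <- 4L * n_per_condition
  withr_seed(seed, {
    stim <- sample(rep(1:4, each = n_per_condition))
    valid <- runif(n) < feedback_validity
  })
  tibble::tibble(
    trial_index = seq_len(n),
    stimulus_id = stim,
    condition = GNG_CONDITIONS[stim],
    correct_action = unname(GNG_CORRECT[GNG_CONDITIONS[stim]]),
    validity_draw = valid
  )
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

cohort_columns <- c("participant_id", "session", "trial_index", "stimulus_id",
                    "condition", "action", "outcome", "feedback_valid")

#' Validate a cohort of behavioural sessions
#'
#' A cohort is a long-format table of trials, one participant-session per
#' \code{participant_id} within a wave.  Each session must contain exactly
#' \code{4 * n_per_condition} trials (144 by default), exactly
#' \code{n_per_condition} per condition, strictly increasing 1-based trial
#' indices, outcomes consistent with condition valence (win trials in
#' \{0, +1\}, avoid-loss trials in \{-1, 0\}), and actions in
#' \{go, nogo, missing\}.
#'
#' @param cohort Data frame with columns \code{participant_id},
#'   \code{session}, \code{trial_index}, \code{stimulus_id},
#'   \code{condition}, \code{action}, \code{outcome}, \code{feedback_valid}.
#' @param n_per_condition Expected trials per condition (default 36).
#' @return The cohort, invisibly, as a tibble; errors name the offending
#'   participant or rows.
#' @export
validate_cohort <- function(cohort, n_per_condition = 36) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    abort(paste("cohort is missing columns:", paste(missing_cols, collapse = ", ")))
  cohort <- tibble::as_tibble(cohort)
  bad_cond <- !cohort$condition %in% GNG_CONDITIONS
  if (any(bad_cond))
    abort(paste("malformed condition in rows:", paste(head(which(bad_cond)), collapse = ", ")))
  bad_act <- !cohort$action %in% c("go", "nogo", "missing")
  if (any(bad_act))
    abort(paste("malformed action in rows:", paste(head(which(bad_act)), collapse = ", ")))
  win <- GNG_VALENCE[cohort$condition] == 1L
  bad_out <- ifelse(win, !cohort$outcome %in% c(0, 1), !cohort$outcome %in% c(-1, 0))
  if (any(bad_out))
    abort(paste("outcome inconsistent with condition valence in rows:",
                paste(head(which(bad_out)), collapse = ", ")))

  n_tr <- 4L * n_per_condition
  per <- dplyr::summarise(
    dplyr::group_by(cohort, .data$participant_id, .data$session),
    n = dplyr::n(),
    ok_idx = all(diff(.data$trial_index) > 0) && .data$trial_index[1] >= 1,
    ok_cond = all(table(factor(.data$condition, GNG_CONDITIONS)) == n_per_condition),
    .groups = "drop"
  )
  bad <- per[per$n != n_tr | !per$ok_idx | !per$ok_cond, ]
  if (nrow(bad))
    abort(paste0("invalid sessions for participant(s): ",
                 paste(unique(bad$participant_id), collapse = ", "),
                 " (expected ", n_tr, " trials, ", n_per_condition,
                 " per condition, strictly increasing trial_index)"))
  dup <- duplicated(per[, c("participant_id", "session")])
  if (any(dup)) abort("duplicate participant_id within a wave")
  invisible(cohort)
}

#' Read and write behavioural cohorts
#'
#' The canonical on-disk format is a long CSV with one row per trial and
#' columns \code{participant_id}, \code{session}, \code{trial_index},
#' \code{stimulus_id}, \code{condition}, \code{action}, \code{outcome},
#' \code{feedback_valid}.  Missing responses are retained as rows with
#' \code{action = "missing"} so that session-global trial indexing (used by
#' held-out-trial procedures) stays aligned.  Reading a MAT-file container is
#' not supported: no MAT v5 reader is available to this package, so deposited
#' MAT data must first be exported to the long CSV layout.
#'
#' @param path File path.
#' @param format Input format; only \code{"long_csv"} is supported.
#' @param n_per_condition Expected trials per condition (default 36).
#' @param validate Whether to validate session invariants on read.
#' @return \code{read_cohort()} returns a validated cohort tibble;
#'   \code{write_cohort()} returns \code{path} invisibly.
#' @export
read_cohort <- function(path, format = c("long_csv", "matfile"),
                        n_per_condition = 36, validate = TRUE) {
  format <- match.arg(format)
  if (format == "matfile")
    abort("matfile input is not supported; export the MAT containers to long CSV first")
  if (!file.exists(path)) abort(paste("file not found:", path))
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session = readr::col_character(),
      trial_index = readr::col_integer(),
      stimulus_id = readr::col_integer(),
      condition = readr::col_character(),
      action = readr::col_character(),
      outcome = readr::col_integer(),
      feedback_valid = readr::col_logical()
    )
  )
  prob <- readr::problems(cohort)
  if (nrow(prob))
    abort(paste("malformed rows in", path, ":",
                paste(unique(prob$row), collapse = ", ")))
  if (validate && nrow(cohort)) validate_cohort(cohort, n_per_condition)
  cohort
}

#' @rdname read_cohort
#' @param cohort A valid cohort table.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort)) validate_cohort(cohort)
  else cohort <- tibble::as_tibble(setNames(
    lapply(cohort_columns, function(x) logical(0)), cohort_columns))
  readr::write_csv(cohort[, cohort_columns], path)
  invisible(path)
}

# split a cohort into a named list of per-participant session tibbles
split_sessions <- function(cohort) {
  split(tibble::as_tibble(cohort), cohort$participant_id)
}
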