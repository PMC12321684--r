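#' Read a trial-level session log
#'
#' Reads a delimited trial log (one row per cue-response event) into a tidy
#' trial table. The expected schema has five columns: `participant_id`,
#' `trial_index` (1-based presentation order), `trial_type` (one of
#' `"rivalry"`, `"mock_red"`, `"mock_blue"`), `cue` (`"R"` or `"B"`, the
#' pattern the participant was asked to imagine) and `response` (`"red"`,
#' `"blue"` or `"mixed"`). Mock trials display a single unambiguous colour and
#' serve as compliance catches; rivalry trials are the ambiguous displays that
#' carry the imagery-priming signal.
#'
#' @param path Path to a delimited text file with a header row. Lines
#'   starting with `#` (e.g. a recorded simulation seed) are ignored.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param case_insensitive If `TRUE`, enum tokens are matched ignoring case
#'   (e.g. `"Mixed"` is accepted for `"mixed"`). Off by default: the schema
#'   spellings are canonical.
#' @return A tibble with the five schema columns, trials sorted by
#'   `participant_id` then `trial_index`.
#' @export
#' @examples
#' log <- simulate_cohort(cohort_spec(n_aphantasic = 2, n_control = 2), seed = 1)
#' tf <- tempfile(fileext = ".csv")
#' write_sessions(log$trials, tf)
#' read_sessions(tf)
read_sessions <- function(path, delim = ",", case_insensitive = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("trial log not found: ", path), class = "brpriming_io_error")
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           comment = "#", progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("trial log is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "brpriming_format_error")
  }
  trials <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    trial_index = suppressWarnings(as.integer(raw$trial_index)),
    trial_type = norm_enum(raw$trial_type, TRIAL_TYPES, "trial_type", case_insensitive),
    cue = norm_enum(raw$cue, CUES, "cue", case_insensitive),
    response = norm_enum(raw$response, RESPONSES, "response", case_insensitive)
  )
  if (anyNA(trials$trial_index)) {
    abort("trial_index must be a positive integer for every row",
          class = "brpriming_integrity_error")
  }
  if (any(trials$trial_index < 1)) {
    abort("trial_index must be >= 1", class = "brpriming_integrity_error")
  }
  dup <- duplicated(trials[, c("participant_id", "trial_index")])
  if (any(dup)) {
    abort(paste0("duplicate (participant_id, trial_index) pair(s), e.g. ",
                 trials$participant_id[dup][1], "/", trials$trial_index[dup][1]),
          class = "brpriming_integrity_error")
  }
  dplyr::arrange(trials, .data$participant_id, .data$trial_index)
}

norm_enum <- function(x, domain, field, case_insensitive) {
  x <- as.character(x)
  if (case_insensitive) {
    x <- domain[match(tolower(x), tolower(domain))]
  }
  bad <- !is.na(x) & !(x %in% domain)
  if (any(bad) || anyNA(x)) {
    offender <- if (anyNA(x)) "<missing>" else x[bad][1]
    abort(paste0("invalid ", field, " token '", offender, "'; expected one of ",
                 paste(domain, collapse = ", ")),
          class = "brpriming_integrity_error")
  }
  x
}

#' Write a trial table to a delimited session log
#'
#' Inverse of [read_sessions()]; a read-write-read round trip preserves the
#' trial table exactly.
#'
#' @param trials Trial tibble in the [read_sessions()] schema.
#' @param path Output file path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path, delim = ",") {
  check_trials(trials)
  readr::write_delim(trials[, TRIAL_COLUMNS], path, delim = delim, progress = FALSE)
  invisible(path)
}

check_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    abort("`trials` must be a data frame of trial records", class = "brpriming_format_error")
  }
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "brpriming_format_error")
  }
  invisible(trials)
}

#' Validate sessions against the compliance and data-quality policy
#'
#' Applies the paradigm's data-cleaning rules per participant: the mock-trial
#' gate (a session passes when at most `max_mock_errors` mock trials were
#' answered with the wrong colour; a mock answer is correct when the response
#' colour matches the displayed colour) and the mixed-trial threshold (the
#' proportion of rivalry trials answered "mixed"). Under the improved priming
#' score mixed-heavy sessions need not be excluded, so crossing the threshold
#' is reported as a flag, not an exclusion; legacy exclusion is available in
#' [score_sessions()].
#'
#' @param trials Trial tibble (see [read_sessions()]).
#' @param max_mock_errors Maximum tolerated wrong mock answers (default 1).
#' @param mixed_threshold Mixed-proportion flag threshold (default 0.20).
#' @return A tibble with one row per participant: `n_nonmock`, `n_mock`,
#'   `mock_errors`, `mixed_proportion`, `cue_imbalance` (absolute difference of
#'   R and B cue counts among rivalry trials), `passes_mock_gate`,
#'   `exceeds_mixed_threshold`, and `no_mock_trials` (warning flag: the gate is
#'   passed vacuously when a session contains no mock trials).
#' @export
validate_sessions <- function(trials, max_mock_errors = 1, mixed_threshold = 0.20) {
  check_trials(trials)
  out <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_nonmock = sum(.data$trial_type == "rivalry"),
      n_mock = sum(.data$trial_type != "rivalry"),
      mock_errors = sum((.data$trial_type == "mock_red" & .data$response != "red") |
                          (.data$trial_type == "mock_blue" & .data$response != "blue")),
      mixed_proportion = ifelse(.data$n_nonmock > 0,
                                sum(.data$trial_type == "rivalry" & .data$response == "mixed") / .data$n_nonmock,
                                NA_real_),
      cue_imbalance = abs(sum(.data$trial_type == "rivalry" & .data$cue == "R") -
                            sum(.data$trial_type == "rivalry" & .data$cue == "B")),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      passes_mock_gate = .data$mock_errors <= max_mock_errors,
      exceeds_mixed_threshold = !is.na(.data$mixed_proportion) &
        .data$mixed_proportion > mixed_threshold,
      no_mock_trials = .data$n_mock == 0
    )
  if (any(out$no_mock_trials)) {
    warn(paste0(sum(out$no_mock_trials),
                " session(s) contain no mock trials; the mock gate passes vacuously"))
  }
  out
}

#' Tally rivalry-trial outcomes into the six-cell cross table
#'
#' Counts, per participant, rivalry trials by (cue, response) cell. The first
#' subscript is the cued (imagined) pattern, the second the reported percept;
#' `M` denotes a mixed percept. Mock trials are never counted. The six cells
#' always sum to the number of rivalry trials.
#'
#' @param trials Trial tibble (see [read_sessions()]).
#' @return A tibble with one row per participant and columns `n_BB`, `n_RR`,
#'   `n_BR`, `n_RB`, `n_BM`, `n_RM`.
#' @export
count_outcomes <- function(trials) {
  check_trials(trials)
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_BB = sum(.data$trial_type == "rivalry" & .data$cue == "B" & .data$response == "blue"),
      n_RR = sum(.data$trial_type == "rivalry" & .data$cue == "R" & .data$response == "red"),
      n_BR = sum(.data$trial_type == "rivalry" & .data$cue == "B" & .data$response == "red"),
      n_RB = sum(.data$trial_type == "rivalry" & .data$cue == "R" & .data$response == "blue"),
      n_BM = sum(.data$trial_type == "rivalry" & .data$cue == "B" & .data$response == "mixed"),
      n_RM = sum(.data$trial_type == "rivalry" & .data$cue == "R" & .data$response == "mixed"),
      .groups = "drop"
    )
}

#' Imagery-consistency bias on mock trials
#'
#' Mock trials display one unambiguous colour, so a compliant observer's
#' response is fixed by the display and should not depend on the imagery cue.
#' The per-participant bias is the proportion of mock trials answered with the
#' cued colour minus the proportion of mock trials whose displayed colour
#' equals the cued colour; 0 indicates no imagery-consistent bias. A
#' cohort-level one-sample test of these values against 0 is provided by
#' [mock_bias_test()].
#'
#' @param trials Trial tibble (see [read_sessions()]).
#' @return A tibble with one row per participant: `n_mock` and `mock_bias`
#'   (`NA` when the session has no mock trials -- undefined, distinct from 0).
#' @export
mock_bias <- function(trials) {
  check_trials(trials)
  trials |>
    dplyr::filter(.data$trial_type != "rivalry") |>
    dplyr::mutate(
      cued_colour = ifelse(.data$cue == "R", "red", "blue"),
      shown_colour = ifelse(.data$trial_type == "mock_red", "red", "blue")
    ) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_mock = dplyr::n(),
      mock_bias = mean(.data$response == .data$cued_colour) -
        mean(.data$shown_colour == .data$cued_colour),
      .groups = "drop"
    ) |>
    dplyr::right_join(
      tibble::tibble(participant_id = unique(trials$participant_id)),
      by = "participant_id"
    ) |>
    dplyr::mutate(n_mock = dplyr::coalesce(.data$n_mock, 0L)) |>
    dplyr::arrange(.data$participant_id)
}
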