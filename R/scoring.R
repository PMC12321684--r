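#' Original imagery-priming score
#'
#' The classic score: the proportion of non-mixed rivalry trials on which the
#' dominant percept matched the previously imagined pattern,
#' \deqn{(n_{B,B} + n_{R,R}) / (n_{B,B} + n_{R,R} + n_{B,R} + n_{R,B}).}
#' Mixed-percept trials are discarded entirely. The score is undefined (`NA`)
#' when every rivalry trial was mixed.
#'
#' @param counts A data frame of outcome counts with columns `n_BB`, `n_RR`,
#'   `n_BR`, `n_RB` (e.g. from [count_outcomes()]); one row per session.
#' @return A numeric vector in `[0, 1]`, `NA` where the denominator is zero.
#' @seealso [priming_score_improved()], [count_outcomes()]
#' @export
#' @examples
#' priming_score_original(data.frame(n_BB = 10, n_RR = 10, n_BR = 5, n_RB = 5))
priming_score_original <- function(counts) {
  check_counts(counts, c("n_BB", "n_RR", "n_BR", "n_RB"))
  num <- counts$n_BB + counts$n_RR
  den <- num + counts$n_BR + counts$n_RB
  ifelse(den > 0, num / den, NA_real_)
}

#' Improved imagery-priming score with half-weighted mixed trials
#'
#' Retains mixed-percept trials instead of discarding them: each mixed trial
#' contributes half a count to the numerator and a full count to the
#' denominator,
#' \deqn{(n_{B,B} + n_{R,R} + 0.5 n_{B,M} + 0.5 n_{R,M}) /
#'       (n_{B,B} + n_{R,R} + n_{B,R} + n_{R,B} + n_{B,M} + n_{R,M}).}
#' A mixed percept is evidence of no priming either way, so mixed trials pull
#' the score towards the 0.5 chance level without ever moving it across 0.5;
#' the non-mixed cells alone decide which side of 0.5 the score falls on. With
#' zero mixed trials the improved and original scores are identical. Undefined
#' (`NA`) only when the session has no rivalry trials at all.
#'
#' @param counts A data frame with columns `n_BB`, `n_RR`, `n_BR`, `n_RB`,
#'   `n_BM`, `n_RM`; one row per session.
#' @return A numeric vector in `[0, 1]`, `NA` where all six cells are zero.
#' @seealso [priming_score_original()], [convergence_curve()]
#' @export
#' @examples
#' priming_score_improved(
#'   data.frame(n_BB = 10, n_RR = 10, n_BR = 0, n_RB = 0, n_BM = 10, n_RM = 10)
#' )
priming_score_improved <- function(counts) {
  check_counts(counts, c("n_BB", "n_RR", "n_BR", "n_RB", "n_BM", "n_RM"))
  num <- counts$n_BB + counts$n_RR + 0.5 * counts$n_BM + 0.5 * counts$n_RM
  den <- counts$n_BB + counts$n_RR + counts$n_BR + counts$n_RB +
    counts$n_BM + counts$n_RM
  ifelse(den > 0, num / den, NA_real_)
}

check_counts <- function(counts, cols) {
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame of outcome counts", class = "brpriming_format_error")
  }
  missing <- setdiff(cols, names(counts))
  if (length(missing) > 0) {
    abort(paste0("`counts` is missing column(s): ", paste(missing, collapse = ", ")),
          class = "brpriming_format_error")
  }
  vals <- unlist(counts[cols], use.names = FALSE)
  if (any(vals < 0 | !is.finite(vals))) {
    abort("outcome counts must be non-negative finite numbers",
          class = "brpriming_integrity_error")
  }
  invisible(counts)
}

#' Improved score as a function of the mixed-trial count
#'
#' Evaluates the improved priming score for a fixed number of congruent and
#' incongruent trials while the mixed-trial count varies. The curve is flat at
#' 0.5 when congruent and incongruent counts are equal, and otherwise
#' converges monotonically towards 0.5 as mixed trials accumulate -- the more
#' non-mixed trials, the flatter the curve.
#'
#' @param n_congruent,n_incongruent Non-negative trial counts.
#' @param mixed_counts Integer vector of mixed-trial counts to evaluate at.
#' @return A tibble with columns `n_mixed` and `score` (`NA` where all three
#'   counts are zero).
#' @export
#' @examples
#' convergence_curve(20, 0, 0:20)
convergence_curve <- function(n_congruent, n_incongruent, mixed_counts) {
  stopifnot(is_scalar_number(n_congruent), is_scalar_number(n_incongruent),
            n_congruent >= 0, n_incongruent >= 0,
            is.numeric(mixed_counts), all(mixed_counts >= 0))
  counts <- tibble::tibble(
    n_BB = n_congruent, n_RR = 0, n_BR = n_incongruent, n_RB = 0,
    n_BM = mixed_counts, n_RM = 0
  )
  tibble::tibble(n_mixed = as.integer(mixed_counts),
                 score = priming_score_improved(counts))
}

#' Perceptual stability across consecutive rivalry trials
#'
#' The dominant percept of one rivalry trial can prime the next: observers
#' whose perception is not disrupted by mental imagery between presentations
#' tend to report the same pattern on consecutive trials. The stability score
#' is the proportion of ordered pairs of successive rivalry trials -- both
#' answered with a non-mixed percept -- whose responses match. By default the
#' rivalry sequence skips over interleaved mock trials; with
#' `break_at_mock = TRUE` a mock trial breaks the adjacency chain instead.
#'
#' @param trials Trial tibble (see [read_sessions()]).
#' @param break_at_mock If `TRUE`, pairs of rivalry trials separated by a mock
#'   trial are not counted as adjacent.
#' @return A tibble with one row per participant: `n_pairs` (eligible pairs)
#'   and `stability` (`NA` when fewer than two rivalry trials or no eligible
#'   pair exists).
#' @export
perceptual_stability <- function(trials, break_at_mock = FALSE) {
  check_trials(trials)
  trials |>
    dplyr::arrange(.data$participant_id, .data$trial_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      stability_pair_tally(.data$trial_type, .data$response, break_at_mock),
      .groups = "drop"
    )
}

stability_pair_tally <- function(trial_type, response, break_at_mock) {
  riv <- trial_type == "rivalry"
  resp <- response[riv]
  if (length(resp) < 2) {
    return(tibble::tibble(n_pairs = 0L, stability = NA_real_))
  }
  adjacent <- rep(TRUE, length(resp) - 1L)
  if (break_at_mock) {
    # a pair is adjacent only if no mock trial sits between the two rivalry trials
    pos <- which(riv)
    adjacent <- diff(pos) == 1L
  }
  eligible <- adjacent & resp[-length(resp)] != "mixed" & resp[-1] != "mixed"
  n_pairs <- sum(eligible)
  tibble::tibble(
    n_pairs = as.integer(n_pairs),
    stability = if (n_pairs > 0) {
      mean((resp[-length(resp)] == resp[-1])[eligible])
    } else NA_real_
  )
}

#' Priming-minus-stability difference score
#'
#' Imagery priming and perceptual stability pull the rivalry response in
#' opposite directions across the imagery-vividness spectrum: stronger imagery
#' raises priming and, by disrupting the lingering percept between trials,
#' lowers stability. Contrasting the two therefore separates weak imagers
#' (stability-dominant) from strong imagers (priming-dominant) better than
#' either score alone. Oriented as `improved - stability` so that larger
#' values correspond to stronger imagery; weak imagers, whose stability
#' typically exceeds their priming, fall on the negative side.
#'
#' @param improved Improved priming score(s).
#' @param stability Perceptual stability score(s).
#' @return `improved - stability`, in `[-1, 1]`; `NA` where either input is
#'   `NA`.
#' @export
difference_score <- function(improved, stability) {
  stopifnot(is.numeric(improved), is.numeric(stability))
  improved - stability
}

#' Score every session in a trial table
#'
#' Computes the full score bundle per participant: both priming scores, the
#' perceptual stability score, the difference score, and the session quality
#' metrics they rest on. Undefined scores are propagated as `NA`, never
#' imputed.
#'
#' @param trials Trial tibble (see [read_sessions()]).
#' @param stability_break_at_mock Passed to [perceptual_stability()].
#' @param exclude_mixed_over Optional legacy exclusion threshold: participants
#'   whose mixed-trial proportion exceeds it are dropped from the result (the
#'   historical practice the improved score makes unnecessary). Dropped ids
#'   are recorded in the `"excluded"` attribute and messaged.
#' @return A tibble of class `br_scores`, one row per participant:
#'   `participant_id`, `n_rivalry`, `n_nonmixed`, `mixed_proportion`,
#'   `original`, `improved`, `stability`, `difference`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_aphantasic = 3, n_control = 3), seed = 7)
#' score_sessions(cohort$trials)
score_sessions <- function(trials, stability_break_at_mock = FALSE,
                           exclude_mixed_over = NULL) {
  check_trials(trials)
  if (nrow(trials) == 0) {
    abort("`trials` contains no trial records", class = "brpriming_integrity_error")
  }
  counts <- count_outcomes(trials)
  stab <- perceptual_stability(trials, break_at_mock = stability_break_at_mock)
  out <- counts |>
    dplyr::mutate(
      n_rivalry = .data$n_BB + .data$n_RR + .data$n_BR + .data$n_RB +
        .data$n_BM + .data$n_RM,
      n_nonmixed = .data$n_rivalry - .data$n_BM - .data$n_RM,
      mixed_proportion = ifelse(.data$n_rivalry > 0,
                                (.data$n_BM + .data$n_RM) / .data$n_rivalry, NA_real_),
      original = priming_score_original(dplyr::pick(dplyr::everything())),
      improved = priming_score_improved(dplyr::pick(dplyr::everything()))
    ) |>
    dplyr::left_join(stab, by = "participant_id") |>
    dplyr::mutate(difference = difference_score(.data$improved, .data$stability)) |>
    dplyr::select("participant_id", "n_rivalry", "n_nonmixed", "mixed_proportion",
                  "original", "improved", "stability", "difference")
  excluded <- character(0)
  if (!is.null(exclude_mixed_over)) {
    stopifnot(is_scalar_number(exclude_mixed_over), exclude_mixed_over >= 0)
    drop <- !is.na(out$mixed_proportion) & out$mixed_proportion > exclude_mixed_over
    excluded <- out$participant_id[drop]
    if (length(excluded) > 0) {
      message(length(excluded), " participant(s) excluded at mixed proportion > ",
              exclude_mixed_over, ": ", paste(excluded, collapse = ", "))
    }
    out <- out[!drop, , drop = FALSE]
  }
  attr(out, "excluded") <- excluded
  class(out) <- c("br_scores", class(out))
  out
}
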