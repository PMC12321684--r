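# Small hand-built trial tables used across test files.

trial_row <- function(id, idx, type, cue, response) {
  tibble::tibble(participant_id = id, trial_index = idx, trial_type = type,
                 cue = cue, response = response)
}

# two participants, two rivalry trials each, balanced cues
two_participant_fixture <- function() {
  dplyr::bind_rows(
    trial_row("p1", 1:2, "rivalry", c("R", "B"), c("red", "blue")),
    trial_row("p2", 1:2, "rivalry", c("B", "R"), c("mixed", "red"))
  )
}

# a session from explicit response/cue/type vectors for one participant
session_fixture <- function(types, cues, responses, id = "p1") {
  trial_row(id, seq_along(types), types, cues, responses)
}

clamp_unit <- function(x) pmin(1, pmax(0, x))

# random outcome-count tables for property tests
random_count_tables <- function(n, max_count = 40, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    n_BB = sample(0:max_count, n, replace = TRUE),
    n_RR = sample(0:max_count, n, replace = TRUE),
    n_BR = sample(0:max_count, n, replace = TRUE),
    n_RB = sample(0:max_count, n, replace = TRUE),
    n_BM = sample(0:max_count, n, replace = TRUE),
    n_RM = sample(0:max_count, n, replace = TRUE)
  ))
}

# simulate a cohort with per-participant mixed-percept baselines drawn
# uniformly from a range, returning scores joined with ground truth
simulate_scored_cohort <- function(n = 100, mixed_lo = 0.4, mixed_hi = 0.95,
                                   seed = 1) {
  stopifnot(n %% 2 == 0)
  truth <- withr::with_seed(seed, tibble::tibble(
    participant_id = sprintf("p%03d", seq_len(n)),
    v = c(rbeta(n / 2, 2, 13), rbeta(n / 2, 6, 3)),
    mixed_base = runif(n, mixed_lo, mixed_hi),
    session_seed = sample.int(.Machine$integer.max - 1L, n)
  ))
  trials <- purrr::pmap(
    truth[, c("participant_id", "v", "mixed_base", "session_seed")],
    function(participant_id, v, mixed_base, session_seed) {
      simulate_session(phenotype(v = v, mixed_base = mixed_base),
                       seed = session_seed, participant_id = participant_id)
    }
  ) |> purrr::list_rbind()
  dplyr::left_join(score_sessions(trials), truth, by = "participant_id")
}
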