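test_that("session logs survive a write-read round trip", {
  trials <- two_participant_fixture()
  tf <- withr::local_tempfile(fileext = ".csv")
  write_sessions(trials, tf)
  back <- read_sessions(tf)
  expect_equal(as.data.frame(back), as.data.frame(trials))
  expect_equal(dplyr::n_distinct(back$participant_id), 2L)
  expect_equal(unname(table(back$participant_id)), c(2L, 2L),
               ignore_attr = TRUE)

  # tab dialect round trip
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_sessions(trials, tf2, delim = "\t")
  expect_equal(as.data.frame(read_sessions(tf2, delim = "\t")),
               as.data.frame(trials))
})

test_that("enum tokens are strict by default and foldable by dialect option", {
  trials <- two_participant_fixture()
  trials$response[3] <- "Mixed"
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(trials, tf)
  expect_error(read_sessions(tf), class = "brpriming_integrity_error")
  folded <- read_sessions(tf, case_insensitive = TRUE)
  expect_equal(folded$response[folded$participant_id == "p2"][1], "mixed")

  trials2 <- two_participant_fixture()
  trials2$cue[1] <- "G"
  readr::write_csv(trials2, tf)
  expect_error(read_sessions(tf), class = "brpriming_integrity_error")
})

test_that("structural defects are reported as named errors", {
  trials <- two_participant_fixture()
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(trials, -"cue"), tf)
  expect_error(read_sessions(tf), "cue", class = "brpriming_format_error")

  dup <- trials
  dup$trial_index[2] <- 1L
  readr::write_csv(dup, tf)
  expect_error(read_sessions(tf), class = "brpriming_integrity_error")

  expect_error(read_sessions(file.path(tempdir(), "nope.csv")),
               class = "brpriming_io_error")
})

test_that("mock gate follows the max-one-wrong-answer policy", {
  # 4 mock trials, 1 answered wrongly: retained
  s <- session_fixture(
    c("rivalry", "mock_red", "mock_red", "mock_blue", "mock_blue", "rivalry"),
    c("R", "B", "R", "B", "R", "B"),
    c("red", "red", "blue", "blue", "blue", "blue")
  )
  rep <- validate_sessions(s)
  expect_equal(rep$n_mock, 4L)
  expect_equal(rep$mock_errors, 1L)
  expect_true(rep$passes_mock_gate)

  # two wrong mock answers: gated out
  s2 <- session_fixture(
    c("mock_red", "mock_blue", "rivalry"),
    c("R", "B", "R"),
    c("blue", "red", "red")
  )
  expect_false(validate_sessions(s2)$passes_mock_gate)
  expect_true(validate_sessions(s2, max_mock_errors = 2)$passes_mock_gate)
})

test_that("mixed proportion and threshold flag are computed per session", {
  s <- session_fixture(
    rep("rivalry", 32),
    rep(c("R", "B"), 16),
    c(rep("mixed", 8), rep(c("red", "blue"), 12))
  )
  rep <- suppressWarnings(validate_sessions(s))
  expect_equal(rep$mixed_proportion, 0.25)
  expect_true(rep$exceeds_mixed_threshold)
  expect_false(suppressWarnings(validate_sessions(s, mixed_threshold = 0.25))$exceeds_mixed_threshold)
  expect_equal(rep$cue_imbalance, 0L)
})

test_that("sessions without mock trials pass the gate vacuously, with a warning flag", {
  s <- session_fixture(rep("rivalry", 4), rep(c("R", "B"), 2),
                       rep(c("red", "blue"), 2))
  expect_warning(rep <- validate_sessions(s), "no mock trials")
  expect_true(rep$passes_mock_gate)
  expect_true(rep$no_mock_trials)
})

test_that("outcome counting tallies rivalry trials only and conserves totals", {
  s <- session_fixture(
    c("rivalry", "rivalry", "rivalry", "rivalry", "mock_red"),
    c("B", "B", "R", "R", "R"),
    c("blue", "mixed", "red", "blue", "red")
  )
  counts <- count_outcomes(s)
  expect_equal(counts$n_BB, 1L)
  expect_equal(counts$n_BM, 1L)
  expect_equal(counts$n_RR, 1L)
  expect_equal(counts$n_RB, 1L)
  expect_equal(counts$n_BR + counts$n_RM, 0L)

  # mock-only session: all cells zero
  m <- session_fixture(c("mock_red", "mock_blue"), c("R", "B"), c("red", "blue"))
  expect_equal(sum(dplyr::select(count_outcomes(m), -"participant_id")), 0L)

  # conservation on simulated sessions
  for (seed in 1:5) {
    sess <- simulate_session(phenotype(v = 0.5, mixed_base = 0.3), seed = seed)
    counts <- count_outcomes(sess)
    expect_equal(counts$n_BB + counts$n_RR + counts$n_BR + counts$n_RB +
                   counts$n_BM + counts$n_RM,
                 sum(sess$trial_type == "rivalry"))
  }
})

test_that("mock bias is the cue-consistent excess over display-cue congruence", {
  # perfect accuracy, cues half-congruent with display: zero bias
  s <- session_fixture(
    c("mock_red", "mock_red", "mock_blue", "mock_blue"),
    c("R", "B", "R", "B"),
    c("red", "red", "blue", "blue")
  )
  expect_equal(mock_bias(s)$mock_bias, 0)

  # display never matches the cue; one response drifts to the cued colour
  s2 <- session_fixture(
    rep("mock_red", 4), rep("B", 4),
    c("blue", "red", "red", "red")
  )
  expect_equal(mock_bias(s2)$mock_bias, 0.25)

  # no mock trials: undefined, not zero
  s3 <- session_fixture(rep("rivalry", 2), c("R", "B"), c("red", "blue"))
  out <- mock_bias(s3)
  expect_true(is.na(out$mock_bias))
  expect_equal(out$n_mock, 0L)
})

test_that("validation reports are pure functions of session and policy", {
  trials <- simulate_cohort(cohort_spec(n_aphantasic = 3, n_control = 3),
                            seed = 3)$trials
  expect_identical(validate_sessions(trials), validate_sessions(trials))
})
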