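test_that("original priming score is the congruent proportion of non-mixed trials", {
  expect_equal(priming_score_original(data.frame(n_BB = 10, n_RR = 10, n_BR = 5, n_RB = 5)),
               20 / 30)
  expect_equal(priming_score_original(data.frame(n_BB = 7, n_RR = 9, n_BR = 0, n_RB = 0)),
               1)
  # all trials mixed: 0/0, undefined
  expect_true(is.na(priming_score_original(
    data.frame(n_BB = 0, n_RR = 0, n_BR = 0, n_RB = 0, n_BM = 5, n_RM = 4)
  )))
})

test_that("improved score half-weights mixed trials in the numerator only", {
  expect_equal(priming_score_improved(
    data.frame(n_BB = 10, n_RR = 10, n_BR = 0, n_RB = 0, n_BM = 10, n_RM = 10)
  ), 0.75)
  # all-mixed session sits exactly at the 0.5 chance level
  expect_equal(priming_score_improved(
    data.frame(n_BB = 0, n_RR = 0, n_BR = 0, n_RB = 0, n_BM = 13, n_RM = 12)
  ), 0.5)
  # no rivalry trials at all: undefined
  expect_true(is.na(priming_score_improved(
    data.frame(n_BB = 0, n_RR = 0, n_BR = 0, n_RB = 0, n_BM = 0, n_RM = 0)
  )))
  expect_error(priming_score_improved(data.frame(n_BB = -1, n_RR = 0, n_BR = 0,
                                                 n_RB = 0, n_BM = 0, n_RM = 0)),
               class = "brpriming_integrity_error")
})

test_that("priming scores obey boundedness, symmetry, betweenness and the zero-mixed identity", {
  tables <- random_count_tables(500, seed = 42)
  orig <- priming_score_original(tables)
  impr <- priming_score_improved(tables)

  expect_true(all(orig >= 0 & orig <= 1, na.rm = TRUE))
  expect_true(all(impr >= 0 & impr <= 1, na.rm = TRUE))

  # relabeling blue <-> red (transpose cue and response consistently) leaves
  # both scores unchanged
  swapped <- dplyr::rename(tables, n_BB = "n_RR", n_RR = "n_BB",
                           n_BR = "n_RB", n_RB = "n_BR",
                           n_BM = "n_RM", n_RM = "n_BM")
  expect_equal(priming_score_original(swapped), orig)
  expect_equal(priming_score_improved(swapped), impr)

  # improved lies weakly between original and 0.5: mixed trials never push the
  # score across the chance level
  ok <- !is.na(orig)
  expect_true(all(impr[ok] >= pmin(orig[ok], 0.5) - 1e-12))
  expect_true(all(impr[ok] <= pmax(orig[ok], 0.5) + 1e-12))

  # with zero mixed cells the two equations coincide exactly
  zero_mixed <- dplyr::mutate(tables, n_BM = 0, n_RM = 0)
  expect_identical(priming_score_improved(zero_mixed),
                   priming_score_original(zero_mixed))
})

test_that("adding mixed trials moves the improved score monotonically towards 0.5", {
  tables <- random_count_tables(200, seed = 7)
  base_dist <- abs(priming_score_improved(tables) - 0.5)
  bumped <- dplyr::mutate(tables, n_BM = n_BM + 3, n_RM = n_RM + 2)
  expect_true(all(abs(priming_score_improved(bumped) - 0.5) <= base_dist + 1e-12,
                  na.rm = TRUE))
})

test_that("convergence curve is flat at 0.5 for balanced counts and monotone otherwise", {
  flat <- convergence_curve(20, 20, 0:40)
  expect_true(all(flat$score == 0.5))

  curve <- convergence_curve(20, 0, c(0, 20))
  expect_equal(curve$score, c(1, 0.75))

  down <- convergence_curve(30, 10, 0:60)$score
  expect_true(all(diff(down) <= 0))
  expect_true(all(down >= 0.5))
  up <- convergence_curve(5, 25, 0:60)$score
  expect_true(all(diff(up) >= 0))
  expect_true(all(up <= 0.5))

  # undefined where all three counts are zero
  expect_true(is.na(convergence_curve(0, 0, 0:1)$score[1]))
})

test_that("more non-mixed trials flatten the convergence curve", {
  small <- convergence_curve(20, 0, 0:10)$score
  large <- convergence_curve(60, 0, 0:10)$score
  expect_true(all(abs(diff(large)) <= abs(diff(small))))
})

test_that("perceptual stability counts matching successive non-mixed rivalry pairs", {
  s <- session_fixture(rep("rivalry", 4), c("R", "B", "R", "B"),
                       c("red", "red", "blue", "blue"))
  expect_equal(perceptual_stability(s)$stability, 2 / 3)

  const <- session_fixture(rep("rivalry", 5), c("R", "B", "R", "B", "R"),
                           rep("red", 5))
  expect_equal(perceptual_stability(const)$stability, 1)

  alt <- session_fixture(rep("rivalry", 6), rep(c("R", "B"), 3),
                         rep(c("red", "blue"), 3))
  expect_equal(perceptual_stability(alt)$stability, 0)

  # pairs touching a mixed response are dropped from both numerator and denominator
  mx <- session_fixture(rep("rivalry", 4), c("R", "B", "R", "B"),
                        c("red", "mixed", "blue", "blue"))
  out <- perceptual_stability(mx)
  expect_equal(out$n_pairs, 1L)
  expect_equal(out$stability, 1)

  # fewer than two rivalry trials: undefined
  one <- session_fixture(c("rivalry", "mock_red"), c("R", "B"), c("red", "red"))
  expect_true(is.na(perceptual_stability(one)$stability))
})

test_that("mock trials are skipped or break the chain depending on policy", {
  s <- session_fixture(
    c("rivalry", "mock_red", "rivalry", "rivalry"),
    c("R", "B", "B", "R"),
    c("red", "red", "red", "blue")
  )
  # default: the mock is transparent, rivalry pairs (1,3) and (3,4)
  expect_equal(perceptual_stability(s)$n_pairs, 2L)
  expect_equal(perceptual_stability(s)$stability, 0.5)
  # breaking at mocks removes the spanning pair
  strict <- perceptual_stability(s, break_at_mock = TRUE)
  expect_equal(strict$n_pairs, 1L)
  expect_equal(strict$stability, 0)
})

test_that("difference score subtracts stability from priming and propagates NA", {
  expect_equal(difference_score(0.7, 0.7), 0)
  expect_equal(difference_score(0.9, 0.6), 0.3)
  expect_true(is.na(difference_score(NA_real_, 0.5)))
  expect_true(is.na(difference_score(0.5, NA_real_)))
  # a strongly stable, weakly primed session lands on the negative side
  expect_lt(difference_score(0.55, 0.83), 0)
})

test_that("score_sessions composes all scores and propagates undefined values", {
  sess <- simulate_session(phenotype(v = 0.6, mixed_base = 0.2), seed = 9)
  bundle <- score_sessions(sess)
  expect_s3_class(bundle, "br_scores")
  expect_false(anyNA(bundle[, c("original", "improved", "stability", "difference")]))
  expect_equal(bundle$n_rivalry, 32L)

  all_mixed <- session_fixture(rep("rivalry", 6), rep(c("R", "B"), 3),
                               rep("mixed", 6))
  b2 <- score_sessions(all_mixed)
  expect_true(is.na(b2$original))
  expect_equal(b2$improved, 0.5)
  expect_true(is.na(b2$stability))

  expect_error(score_sessions(two_participant_fixture()[0, ]),
               class = "brpriming_integrity_error")
})

test_that("score bundles are stable across a write-read round trip", {
  trials <- simulate_cohort(cohort_spec(n_aphantasic = 4, n_control = 4),
                            seed = 21)$trials
  tf <- withr::local_tempfile(fileext = ".csv")
  write_sessions(trials, tf)
  expect_equal(as.data.frame(score_sessions(read_sessions(tf))),
               as.data.frame(score_sessions(trials)))
})

test_that("legacy mixed-proportion exclusion drops and lists participants", {
  trials <- dplyr::bind_rows(
    session_fixture(rep("rivalry", 10), rep(c("R", "B"), 5),
                    c(rep("mixed", 6), rep("red", 4)), id = "heavy"),
    session_fixture(rep("rivalry", 10), rep(c("R", "B"), 5),
                    c("mixed", rep(c("red", "blue"), 4), "red"), id = "light")
  )
  expect_message(kept <- score_sessions(trials, exclude_mixed_over = 0.20),
                 "heavy")
  expect_equal(kept$participant_id, "light")
  expect_equal(attr(kept, "excluded"), "heavy")
  # default behaviour: flag-only, nobody dropped
  expect_equal(nrow(score_sessions(trials)), 2L)
})
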