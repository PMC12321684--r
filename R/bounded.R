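#' Sample questionnaire/task score pairs under the one-sided imagery bound
#'
#' Generative model behind the correlation-ceiling argument: a person may
#' hold imagery representations they do not experience (unconscious imagery,
#' high task score with low self-report), but reporting vivid imagery without
#' any underlying representation is implausible -- so the rivalry task score
#' is assumed to be at least the normalised self-report. Pairs are sampled
#' uniformly on the unit square and rejected until `n` pairs satisfying
#' `br_score >= vviq_norm` are accepted, i.e. the accepted pairs are uniform
#' on the triangle above the diagonal.
#'
#' @param n Number of accepted pairs (>= 2).
#' @param seed Integer seed; identical seeds give identical pairs.
#' @param constrained If `FALSE`, the rejection step is skipped (independent
#'   uniform control condition).
#' @return A tibble with columns `vviq_norm` and `br_score`.
#' @export
#' @examples
#' pairs <- sample_bounded_pairs(1000, seed = 1)
#' all(pairs$br_score >= pairs$vviq_norm)
sample_bounded_pairs <- function(n, seed, constrained = TRUE) {
  stopifnot(is_scalar_number(n), n >= 2)
  withr::with_seed(as.integer(seed), {
    x <- numeric(0)
    y <- numeric(0)
    while (length(x) < n) {
      m <- max(64L, 3L * (n - length(x)))
      xv <- runif(m)
      yv <- runif(m)
      keep <- if (constrained) yv >= xv else rep(TRUE, m)
      x <- c(x, xv[keep])
      y <- c(y, yv[keep])
    }
    tibble::tibble(vviq_norm = x[seq_len(n)], br_score = y[seq_len(n)])
  })
}

#' Correlation induced by the one-sided imagery bound
#'
#' Repeatedly samples constrained pairs with [sample_bounded_pairs()] and
#' averages the Pearson correlation between self-report and task score across
#' replicates. Under the uniform-triangle model the population correlation is
#' exactly 1/2 (marginal means 1/3 and 2/3, variances 1/18, covariance 1/36),
#' which is the ceiling any questionnaire-validated task score can reach when
#' unconscious imagery is allowed but imagery experience without
#' representation is ruled out.
#'
#' @param n Pairs per replicate (>= 30).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer master seed; replicate seeds derived deterministically.
#' @param constrained Passed to [sample_bounded_pairs()].
#' @return A one-row tibble: `mean_r`, `sd_r` (across replicates), `ci_low`,
#'   `ci_high` (normal-approximation CI of the mean), `n`, `n_reps`.
#' @export
#' @examples
#' bounded_correlation(n = 1000, n_reps = 5, seed = 1)
bounded_correlation <- function(n = 1000, n_reps = 20, seed, constrained = TRUE) {
  stopifnot(is_scalar_number(n), n >= 30, is_scalar_number(n_reps), n_reps >= 1)
  rep_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n_reps))
  rs <- purrr::map_dbl(rep_seeds, function(s) {
    p <- sample_bounded_pairs(n, seed = s, constrained = constrained)
    pearson(p$vviq_norm, p$br_score)$r
  })
  se <- if (n_reps > 1) sd(rs) / sqrt(n_reps) else NA_real_
  tibble::tibble(mean_r = mean(rs), sd_r = if (n_reps > 1) sd(rs) else NA_real_,
                 ci_low = mean(rs) - qnorm(0.975) * se,
                 ci_high = mean(rs) + qnorm(0.975) * se,
                 n = as.integer(n), n_reps = as.integer(n_reps))
}
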