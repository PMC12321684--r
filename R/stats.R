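#' Pearson correlation with pairwise deletion
#'
#' Product-moment correlation over complete pairs, reporting the effective
#' sample size actually used. Undefined score entries (`NA`) are dropped
#' pairwise, never imputed.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble with `r` (`NA` if either variable has zero
#'   variance among complete pairs) and `n` (complete pairs used).
#' @export
pearson <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) {
    abort("fewer than 3 complete pairs", class = "brpriming_stat_error")
  }
  r <- if (sd(x[ok]) == 0 || sd(y[ok]) == 0) NA_real_ else cor(x[ok], y[ok])
  tibble::tibble(r = r, n = as.integer(n))
}

#' Compare two dependent correlations sharing one variable
#'
#' Tests whether two predictors correlate differently with a common criterion
#' measured on the same sample, using Steiger's z for dependent overlapping
#' correlations: both correlations are Fisher z-transformed and their
#' difference standardised by the asymptotic covariance implied by the
#' correlation between the two predictors (evaluated at the pooled
#' correlation). The one-tailed p (default) addresses the directional
#' question "does the first predictor explain more variance than the second";
#' two-tailed is available via `tails`.
#'
#' @param r_y1 Correlation of predictor 1 with the criterion.
#' @param r_y2 Correlation of predictor 2 with the criterion.
#' @param r_12 Correlation between the two predictors.
#' @param n Sample size (>= 10).
#' @param tails `"one"` (default) or `"two"`.
#' @return A one-row tibble with `z`, `p` and `tails`. `z > 0` when
#'   `r_y1 > r_y2`; swapping the two predictors flips the sign.
#' @export
#' @examples
#' compare_dependent_correlations(0.5, 0.3, 0.6, n = 100)
compare_dependent_correlations <- function(r_y1, r_y2, r_12, n,
                                           tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(is_scalar_number(r_y1), abs(r_y1) < 1,
            is_scalar_number(r_y2), abs(r_y2) < 1,
            is_scalar_number(r_12), abs(r_12) < 1,
            is_scalar_number(n), n >= 10)
  # the three correlations must form a valid (PSD) correlation matrix
  det3 <- 1 + 2 * r_y1 * r_y2 * r_12 - r_y1^2 - r_y2^2 - r_12^2
  if (det3 < -1e-12) {
    abort("correlation triple (r_y1, r_y2, r_12) is not positive semidefinite",
          class = "brpriming_stat_error")
  }
  z1 <- atanh(r_y1)
  z2 <- atanh(r_y2)
  rm2 <- ((r_y1 + r_y2) / 2)^2
  cov12 <- (r_12 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r_12^2)) /
    (1 - rm2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov12))
  p <- if (tails == "one") pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  tibble::tibble(z = z, p = p, tails = tails)
}

#' Ratio of explained variances
#'
#' How many times more criterion variance one predictor explains than
#' another: the ratio of their coefficients of determination.
#'
#' @param r2_baseline Baseline R-squared (> 0).
#' @param r2_improved Comparison R-squared.
#' @return `r2_improved / r2_baseline`.
#' @export
#' @examples
#' variance_ratio(0.056, 0.093)
variance_ratio <- function(r2_baseline, r2_improved) {
  stopifnot(is_scalar_number(r2_baseline), is_scalar_number(r2_improved),
            r2_improved >= 0)
  if (r2_baseline <= 0) {
    abort("baseline R-squared must be > 0", class = "brpriming_stat_error")
  }
  r2_improved / r2_baseline
}

#' Welch two-sample comparison with Hedges g
#'
#' Unequal-variance t test (Welch-Satterthwaite degrees of freedom) plus the
#' bias-corrected standardised mean difference (Hedges g: Cohen's d on the
#' pooled SD, scaled by the small-sample correction
#' `1 - 3 / (4 (n1 + n2 - 2) - 1)`). `NA` entries are dropped per group.
#'
#' @param a,b Numeric vectors (each with >= 2 non-missing values).
#' @return A one-row tibble: `t`, `df`, `p` (two-sided), `hedges_g`, `n1`,
#'   `n2`.
#' @export
group_compare <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 non-missing values", class = "brpriming_stat_error")
  }
  if (var(a) == 0 && var(b) == 0) {
    abort("both groups have zero variance", class = "brpriming_stat_error")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  d <- (mean(a) - mean(b)) / sp
  g <- d * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, hedges_g = g,
                 n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Cohort-level test of imagery-consistent mock bias
#'
#' One-sample t test of the per-participant mock bias values (see
#' [mock_bias()]) against 0. A non-significant result supports task
#' compliance: responses on unambiguous catch displays do not drift towards
#' the imagined colour.
#'
#' @param bias Numeric vector of per-participant mock bias values; `NA`
#'   (sessions without mock trials) dropped.
#' @return A one-row tibble: `mean_bias`, `t`, `df`, `p`, `n`.
#' @export
mock_bias_test <- function(bias) {
  stopifnot(is.numeric(bias))
  bias <- bias[!is.na(bias)]
  if (length(bias) < 2) {
    abort("need at least 2 non-missing bias values", class = "brpriming_stat_error")
  }
  tt <- t.test(bias, mu = 0)
  tibble::tibble(mean_bias = mean(bias), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 n = length(bias))
}

#' Median-split comparison of the two priming scores
#'
#' Splits a scored cohort at the median of a quality variable (by default the
#' number of non-mixed trials), then, within each subset, correlates both
#' priming scores with the VVIQ and tests their difference with
#' [compare_dependent_correlations()]. The improved score's advantage is
#' expected to concentrate in the low subset, where mixed trials dominate and
#' the original score rests on few observations. Ties at the median go to the
#' low subset.
#'
#' @param scores A score tibble from [score_sessions()] (or any data frame
#'   with `original`, `improved` and the split column).
#' @param vviq Numeric vector of VVIQ totals aligned with `scores` rows.
#' @param split_on Name of the column to split at the median (default
#'   `"n_nonmixed"`).
#' @param min_per_subset Minimum participants per subset (default 10).
#' @return A tibble with one row per subset (`"low"`, `"high"`): `n`, median
#'   of the split variable, `r_original`, `r_improved`, `z`, `p` (one-tailed,
#'   improved vs original).
#' @export
median_split_analysis <- function(scores, vviq, split_on = "n_nonmixed",
                                  min_per_subset = 10) {
  stopifnot(is.data.frame(scores), is.numeric(vviq),
            nrow(scores) == length(vviq))
  if (!split_on %in% names(scores)) {
    abort(paste0("split column not found: ", split_on), class = "brpriming_format_error")
  }
  x <- scores[[split_on]]
  if (length(unique(x[!is.na(x)])) < 2) {
    abort("split variable is constant; median split is degenerate",
          class = "brpriming_stat_error")
  }
  med <- median(x, na.rm = TRUE)
  subset_id <- ifelse(x <= med, "low", "high")
  if (min(table(subset_id)) < min_per_subset) {
    abort(paste0("fewer than ", min_per_subset, " participants in one subset"),
          class = "brpriming_stat_error")
  }
  purrr::map(c(low = "low", high = "high"), function(s) {
    idx <- which(subset_id == s)
    r_o <- pearson(scores$original[idx], vviq[idx])
    r_i <- pearson(scores$improved[idx], vviq[idx])
    r_oi <- pearson(scores$original[idx], scores$improved[idx])
    cmp <- compare_dependent_correlations(r_i$r, r_o$r, r_oi$r, n = r_i$n)
    tibble::tibble(subset = s, n = length(idx),
                   split_median = med,
                   r_original = r_o$r, r_improved = r_i$r,
                   z = cmp$z, p = cmp$p)
  }) |>
    purrr::list_rbind()
}
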