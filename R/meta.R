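#' Random-effects meta-analysis of correlations (DerSimonian-Laird)
#'
#' Pools study-level correlation coefficients under the moment-based
#' random-effects model: each r is Fisher z-transformed with within-study
#' variance `1/(n - 3)`, the between-study variance tau-squared is estimated
#' by the DerSimonian-Laird moment estimator from Cochran's Q, and the
#' inverse-variance pooled z is back-transformed to r. Heterogeneity is
#' summarised by Q (with df = k - 1) and `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' Optionally, influential studies are removed iteratively: while any study's
#' standardised residual `(z_i - z_pooled)/sqrt(v_i + tau2)` exceeds
#' `residual_threshold` in absolute value (and more than two studies remain),
#' the largest offender is dropped and the model refit.
#'
#' @param effects A data frame with columns `study_id`, `r` (each strictly
#'   inside (-1, 1)) and `n` (each >= 4).
#' @param residual_threshold Absolute standardised-residual threshold for
#'   iterative exclusion (e.g. 3), or `NULL` (default) for no exclusion.
#' @param conf_level Confidence level for the pooled interval (default 0.95).
#' @return An object of class `dl_meta`: a list with `pooled_r`, `ci_low`,
#'   `ci_high`, `Q`, `df`, `I2`, `tau2`, `k`, `p` (two-sided, pooled r vs 0),
#'   `studies` (per-study tibble with weights, Fisher z and standardised
#'   residuals) and `excluded` (exclusion trace tibble). Use [tidy()] for the
#'   per-study table and [glance()] for the pooled summary.
#' @export
#' @examples
#' effects <- data.frame(
#'   study_id = c("a", "b", "c"),
#'   r = c(0.2, 0.35, 0.28), n = c(50, 100, 80)
#' )
#' glance(dl_meta(effects))
dl_meta <- function(effects, residual_threshold = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(effects))
  missing <- setdiff(c("study_id", "r", "n"), names(effects))
  if (length(missing) > 0) {
    abort(paste0("`effects` is missing column(s): ", paste(missing, collapse = ", ")),
          class = "brpriming_format_error")
  }
  if (nrow(effects) < 2) {
    abort("meta-analysis requires at least 2 studies", class = "brpriming_stat_error")
  }
  if (any(abs(effects$r) >= 1)) {
    abort("study correlations must lie strictly inside (-1, 1)",
          class = "brpriming_stat_error")
  }
  if (any(effects$n < 4)) {
    abort("every study needs n >= 4 (Fisher-z variance 1/(n-3))",
          class = "brpriming_stat_error")
  }
  keep <- effects
  excluded <- tibble::tibble(study_id = character(0), std_residual = numeric(0),
                             step = integer(0))
  step <- 0L
  repeat {
    fit <- dl_fit(keep, conf_level)
    if (is.null(residual_threshold)) break
    worst <- which.max(abs(fit$studies$std_residual))
    if (abs(fit$studies$std_residual[worst]) <= residual_threshold ||
        nrow(keep) <= 2) {
      break
    }
    step <- step + 1L
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      study_id = fit$studies$study_id[worst],
      std_residual = fit$studies$std_residual[worst],
      step = step
    ))
    keep <- keep[keep$study_id != fit$studies$study_id[worst], , drop = FALSE]
  }
  fit$excluded <- excluded
  fit
}

dl_fit <- function(effects, conf_level) {
  zi <- atanh(effects$r)
  vi <- 1 / (effects$n - 3)
  wi <- 1 / vi
  z_fixed <- sum(wi * zi) / sum(wi)
  Q <- sum(wi * (zi - z_fixed)^2)
  df <- nrow(effects) - 1L
  tau2 <- max(0, (Q - df) / (sum(wi) - sum(wi^2) / sum(wi)))
  ws <- 1 / (vi + tau2)
  z_pooled <- sum(ws * zi) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  crit <- qnorm(1 - (1 - conf_level) / 2)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  studies <- tibble::tibble(
    study_id = effects$study_id, r = effects$r, n = as.integer(effects$n),
    z = zi, vi = vi,
    weight = ws / sum(ws),
    ci_low = tanh(zi - crit * sqrt(vi)),
    ci_high = tanh(zi + crit * sqrt(vi)),
    std_residual = (zi - z_pooled) / sqrt(vi + tau2)
  )
  structure(list(
    pooled_r = tanh(z_pooled),
    ci_low = tanh(z_pooled - crit * se),
    ci_high = tanh(z_pooled + crit * se),
    Q = Q, df = df, I2 = I2, tau2 = tau2, k = nrow(effects),
    p = 2 * pnorm(-abs(z_pooled / se)),
    conf_level = conf_level,
    studies = studies
  ), class = "dl_meta")
}

#' @export
print.dl_meta <- function(x, ...) {
  cat("Random-effects meta-analysis of correlations (DerSimonian-Laird)\n")
  cat(sprintf("  k = %d studies, pooled r = %.3f [%.3f, %.3f], p = %.4g\n",
              x$k, x$pooled_r, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  Q(%d) = %.2f, I2 = %.1f%%, tau2 = %.4f\n", x$df, x$Q, x$I2, x$tau2))
  if (nrow(x$excluded %||% tibble::tibble()) > 0) {
    cat("  excluded:", paste(x$excluded$study_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-study table of a pooled meta-analysis
#'
#' @param x A `dl_meta` object.
#' @param ... Unused.
#' @return The per-study tibble (forest-plot ready: study, r, CI bounds,
#'   relative weight, standardised residual).
#' @method tidy dl_meta
#' @export
tidy.dl_meta <- function(x, ...) {
  x$studies
}

#' One-row summary of a pooled meta-analysis
#'
#' @param x A `dl_meta` object.
#' @param ... Unused.
#' @return A one-row tibble with the pooled estimate, its CI, heterogeneity
#'   statistics and the number of studies retained.
#' @method glance dl_meta
#' @export
glance.dl_meta <- function(x, ...) {
  tibble::tibble(pooled_r = x$pooled_r, ci_low = x$ci_low, ci_high = x$ci_high,
                 p = x$p, Q = x$Q, df = x$df, I2 = x$I2, tau2 = x$tau2,
                 k = x$k, n_excluded = nrow(x$excluded %||% tibble::tibble()))
}
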