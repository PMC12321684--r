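#' Line-plot matrix of the improved score's convergence towards 0.5
#'
#' For each combination of congruent and incongruent trial counts, draws the
#' improved priming score as a function of the mixed-trial count: flat at 0.5
#' when congruent equals incongruent, monotone towards 0.5 otherwise, flatter
#' the more non-mixed trials there are.
#'
#' @param congruent,incongruent Vectors of trial counts defining the facet
#'   grid (defaults 0, 20, 40, 60).
#' @param mixed_max Largest mixed-trial count on the x axis (default 60).
#' @return A ggplot object.
#' @export
plot_convergence <- function(congruent = c(0, 20, 40, 60),
                             incongruent = c(0, 20, 40, 60),
                             mixed_max = 60) {
  grid <- tidyr::expand_grid(n_congruent = congruent, n_incongruent = incongruent)
  curves <- purrr::pmap(grid, function(n_congruent, n_incongruent) {
    dplyr::mutate(convergence_curve(n_congruent, n_incongruent, 0:mixed_max),
                  n_congruent = n_congruent, n_incongruent = n_incongruent)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(position = dplyr::case_when(
      .data$n_congruent > .data$n_incongruent ~ "above 0.5",
      .data$n_congruent < .data$n_incongruent ~ "below 0.5",
      TRUE ~ "at 0.5"
    ))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$n_mixed, y = .data$score,
                                       colour = .data$position)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$n_incongruent),
      cols = ggplot2::vars(.data$n_congruent),
      labeller = ggplot2::label_both
    ) +
    ggplot2::scale_colour_manual(values = c("above 0.5" = "#2e7d32",
                                            "at 0.5" = "grey40",
                                            "below 0.5" = "#c62828")) +
    ggplot2::labs(x = "number of mixed trials", y = "improved priming score",
                  colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scored cohort: original versus improved priming score
#'
#' Scatter of the two priming scores per participant, coloured by the
#' session's mixed-trial proportion. Points off the identity line are the
#' sessions where retaining mixed trials changes the score -- the improved
#' score shrinks mixed-heavy sessions towards 0.5.
#'
#' @param object A `br_scores` tibble from [score_sessions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot br_scores
#' @export
autoplot.br_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$original, y = .data$improved,
                                       colour = .data$mixed_proportion)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey80") +
    ggplot2::geom_point(na.rm = TRUE, alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::scale_colour_viridis_c(name = "mixed\nproportion") +
    ggplot2::labs(x = "original priming score", y = "improved priming score") +
    ggplot2::theme_minimal()
}

#' Forest plot of a pooled meta-analysis
#'
#' @param object A `dl_meta` object from [dl_meta()].
#' @param ... Unused.
#' @return A ggplot object with per-study estimates (point size proportional
#'   to relative weight) and the pooled estimate with its CI band.
#' @method autoplot dl_meta
#' @export
autoplot.dl_meta <- function(object, ...) {
  studies <- tidy(object)
  studies$study_id <- factor(studies$study_id, levels = rev(studies$study_id))
  ggplot2::ggplot(studies, ggplot2::aes(x = .data$r, y = .data$study_id)) +
    ggplot2::annotate("rect", xmin = object$ci_low, xmax = object$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$pooled_r, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "correlation (r)", y = NULL) +
    ggplot2::theme_minimal()
}
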