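#' Plot per-condition performance for a cohort
#'
#' Boxplots of the fraction of correct responses per condition and phase,
#' the task's standard descriptive display: the Pavlovian-congruent
#' conditions (G2W, NG2AL) typically outperform the incongruent ones
#' (NG2W, G2AL), most strongly in early trials.
#'
#' @param cohort A validated cohort.
#' @param phases Phases to display.
#' @return A ggplot object.
#' @export
plot_performance <- function(cohort, phases = c("early", "late")) {
  s <- performance_summary(cohort, phases)
  long <- tidyr::pivot_longer(s, dplyr::all_of(GNG_CONDITIONS),
                              names_to = "condition", values_to = "fraction")
  long$condition <- factor(long$condition, GNG_CONDITIONS)
  long$phase <- factor(long$phase, phases)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$fraction,
                                     fill = .data$condition)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.alpha = 0.3) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(y = "fraction correct", x = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_performance Autoplot for a fitted model: per-subject
#'   natural-space parameter distributions.
#' @param object A \code{gng_fit}.
#' @param ... Unused.
#' @export
autoplot.gng_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$subjects[, c("participant_id", object$model$params)],
    -"participant_id", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(title = paste("MAP parameter estimates:", object$model$name),
                  x = "natural-space value", y = "participants") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_performance Autoplot for a mixture clustering: the joint
#'   fit-value distribution coloured by hard assignment.
#' @export
autoplot.gng_clusters <- function(object, ...) {
  cen <- tidy.gng_clusters(object)
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$mean_wave1, y = .data$mean_wave2,
                                    size = .data$weight,
                                    colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "model fit, wave 1", y = "model fit, wave 2",
                  colour = "cluster", size = "weight") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_performance Autoplot for a bias experiment: distribution
#'   of informed-minus-agnostic hidden-trial predictive log-likelihood.
#' @export
autoplot.gng_bias_experiment <- function(object, ...) {
  df <- dplyr::mutate(object$epochs,
                      d = .data$log_ph_informed - .data$log_ph_agnostic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 60, fill = "darkorange", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~eps_true, scales = "free") +
    ggplot2::labs(x = "informed - agnostic log p(hidden | visible)",
                  y = "epochs") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_performance Scatter of a measure across waves with the
#'   identity line, the standard test-retest display.
#' @param table1,table2 Per-subject tables with \code{participant_id} and
#'   the measure.
#' @param measure Column name to plot.
#' @export
plot_retest <- function(table1, table2, measure) {
  m <- dplyr::inner_join(table1, table2, by = "participant_id",
                         suffix = c("_1", "_2"))
  ggplot2::ggplot(m, ggplot2::aes(x = .data[[paste0(measure, "_1")]],
                                  y = .data[[paste0(measure, "_2")]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = paste(measure, "(wave 1)"),
                  y = paste(measure, "(wave 2)")) +
    ggplot2::theme_minimal()
}
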