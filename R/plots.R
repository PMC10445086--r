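# ggplot2 views of the experiment's result objects.

#' Plot an error sweep
#'
#' Per-repetition points and the per-level mean of a hold-out metric
#' against the injected error level.
#'
#' @param object A `sweep_result`.
#' @param metric One of `"mean_absolute_error"`, `"mean_relative_error"`,
#'   `"correlation"`, `"n_selected_sites"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object,
                                  metric = c("mean_absolute_error",
                                             "mean_relative_error",
                                             "correlation",
                                             "n_selected_sites"), ...) {
  metric <- match.arg(metric)
  df <- object$summaries
  means <- dplyr::summarise(dplyr::group_by(df, .data$level),
                            value = mean(.data[[metric]]), .groups = "drop")
  base_val <- switch(metric,
                     mean_absolute_error = object$baseline$mean_absolute_error,
                     mean_relative_error = object$baseline$mean_relative_error,
                     correlation = object$baseline$correlation,
                     n_selected_sites = object$baseline$n_selected_sites)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.35, size = 1) +
    ggplot2::geom_line(data = means, ggplot2::aes(y = .data$value),
                       linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = base_val, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = "Injected training-age error (%)", y = metric,
                  title = "Hold-out degradation under calibration-age error",
                  subtitle = "dashed line: baseline clock (0% error)") +
    ggplot2::theme_minimal()
}

#' Plot a threshold report
#'
#' Cohen's d per level with the fitted effect-size line and the
#' conventional small/medium/large cutoffs; the detected small-effect
#' threshold is marked when reached.
#'
#' @param object A `threshold_report`.
#' @param thresholds Cutoffs from [effect_thresholds()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.threshold_report <- function(object, thresholds = effect_thresholds(),
                                      ...) {
  df <- object$per_level
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$d)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(thresholds$small, thresholds$medium,
                                       thresholds$large),
                        linetype = "dotted",
                        colour = c("#1b7837", "#ff7f00", "#b2182b")) +
    ggplot2::labs(x = "Injected training-age error (%)", y = "Cohen's d",
                  title = "Effect size of calibration-age error") +
    ggplot2::theme_minimal()
  if (!is.null(object$effect_model)) {
    p <- p + ggplot2::geom_abline(slope = object$effect_model$slope,
                                  intercept = object$effect_model$intercept,
                                  colour = "#2166ac")
  }
  d_cross <- object$thresholds$level[object$thresholds$criterion == "d_small"]
  if (!is.na(d_cross)) {
    p <- p + ggplot2::geom_vline(xintercept = d_cross, linetype = "dashed")
  }
  p
}

#' Plot an effect-size model over its fitted points
#'
#' @param object An `effect_size_model`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.effect_size_model <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(x = "Injected training-age error (%)", y = "Mean Cohen's d",
                  title = "Linear effect-size model") +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data,
                                 ggplot2::aes(x = .data$level,
                                              y = .data$mean_d))
  } else {
    p <- p + ggplot2::xlim(0, 100)
  }
  p
}
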