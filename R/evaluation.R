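# Hold-out performance of a clock is summarised by three measures used
# throughout the epigenetic-clock literature: the Pearson correlation
# between predicted and true age, the mean absolute error in age units, and
# the mean relative error as a percentage of each individual's true age.

#' Per-sample absolute prediction errors
#'
#' @param predicted,true Numeric vectors of equal length; `true` ages must
#'   be positive.
#' @return `|predicted - true|`, element-wise.
#' @export
absolute_errors <- function(predicted, true) {
  if (length(predicted) != length(true)) {
    stop_data(sprintf("Length mismatch: %d predictions vs %d true ages.",
                      length(predicted), length(true)))
  }
  if (anyNA(predicted) || anyNA(true)) stop_data("Missing values in ages.")
  abs(predicted - true)
}

#' Per-sample relative prediction errors (percent)
#'
#' Each absolute error is scaled by that individual's true age, so a
#' 2-year miss counts more for a juvenile than for an old adult.
#'
#' @inheritParams absolute_errors
#' @return `|predicted - true| / true * 100`, element-wise.
#' @export
relative_errors <- function(predicted, true) {
  err <- absolute_errors(predicted, true)
  if (any(true <= 0)) {
    stop_data("Relative error is undefined for non-positive true ages.")
  }
  err / true * 100
}

#' Summarise hold-out performance of a clock
#'
#' @param predicted,true Predicted and true ages on the test partition.
#' @param model Optional `clock_model`, used to report the selected-site
#'   count.
#' @param center Aggregation for the error summaries: `"mean"` (default) or
#'   `"median"`.
#' @return A `performance_summary`: correlation, mean absolute error, mean
#'   relative error, selected-site count, and the raw per-sample error
#'   vectors the downstream t-tests consume.
#' @export
summarize_performance <- function(predicted, true, model = NULL,
                                  center = c("mean", "median")) {
  center <- match.arg(center)
  abs_err <- absolute_errors(predicted, true)
  rel_err <- relative_errors(predicted, true)
  agg <- if (center == "mean") mean else median
  r <- if (length(true) < 3L || sd(true) == 0 || sd(predicted) == 0) {
    warn("Correlation undefined (fewer than 3 test samples or zero variance); reported as NA.")
    NA_real_
  } else {
    stats::cor(predicted, true)
  }
  structure(list(
    correlation = r,
    mean_absolute_error = agg(abs_err),
    mean_relative_error = agg(rel_err),
    n_selected_sites = if (is.null(model)) NA_integer_ else count_selected_sites(model),
    per_sample_abs = abs_err,
    per_sample_rel = rel_err,
    n_test = length(true),
    center = center),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> n_test = %d\n", x$n_test))
  cat(sprintf("  r = %.3f, %s abs error = %.3f, %s rel error = %.2f%%",
              x$correlation, x$center, x$mean_absolute_error,
              x$center, x$mean_relative_error))
  if (!is.na(x$n_selected_sites)) {
    cat(sprintf(", %d CpG sites", x$n_selected_sites))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.performance_summary <- function(x, ...) {
  tibble(correlation = x$correlation,
         mean_absolute_error = x$mean_absolute_error,
         mean_relative_error = x$mean_relative_error,
         n_selected_sites = x$n_selected_sites,
         n_test = x$n_test)
}
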