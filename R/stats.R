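# Detection instruments for excess calibration error: a two-sample t-test
# on per-sample prediction errors, Cohen's d with the conventional
# small/medium/large cutoffs, and an ordinary-least-squares model of mean
# effect size against the injected error percentage, whose inversion gives
# the tolerance threshold.

#' Conventional effect-size and significance cutoffs
#'
#' @return List with `small` (0.2), `medium` (0.5), `large` (0.8) Cohen's d
#'   cutoffs and the significance level `alpha` (0.05).
#' @export
effect_thresholds <- function() {
  list(small = 0.2, medium = 0.5, large = 0.8, alpha = 0.05)
}

#' Unpaired two-sample t-test on error vectors
#'
#' Student's pooled-variance test by default, matching the pooled standard
#' deviation used by [cohens_d()]; set `var_equal = FALSE` for the Welch
#' form. Degenerate inputs are handled explicitly: two constant samples
#' with equal means give `p = 1`; constant samples with different means give
#' `p = 0` with a warning, since the test statistic is unbounded.
#'
#' @param x,y Numeric vectors (each length >= 2), e.g. baseline vs
#'   perturbed per-sample errors.
#' @param var_equal Assume equal variances (Student) or not (Welch).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_x`, `mean_y`,
#'   `method`.
#' @export
unpaired_t_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_data("Both samples need at least 2 observations.")
  }
  if (anyNA(x) || anyNA(y)) stop_data("Missing values in test input.")
  method <- if (var_equal) "student" else "welch"
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(statistic = 0, df = NA_real_, p_value = 1,
                    mean_x = mean(x), mean_y = mean(y), method = method))
    }
    warn("Both samples are constant with different means; p-value reported as 0.")
    return(tibble(statistic = sign(mean(y) - mean(x)) * Inf, df = NA_real_,
                  p_value = 0, mean_x = mean(x), mean_y = mean(y),
                  method = method))
  }
  ht <- stats::t.test(y, x, var.equal = var_equal)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y),
         method = method)
}

#' Cohen's d between two error samples
#'
#' Standardised mean difference `(mean(y) - mean(x)) / s_pooled` with the
#' pooled standard deviation
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#' With `x` the baseline errors and `y` the perturbed-model errors, d is
#' positive when perturbation makes predictions worse.
#'
#' @param x Baseline sample (length >= 2).
#' @param y Comparison sample (length >= 2).
#' @return Cohen's d (signed scalar).
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_data("Both samples need at least 2 observations.")
  }
  if (anyNA(x) || anyNA(y)) stop_data("Missing values in effect-size input.")
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) {
    stop_data("Pooled standard deviation is zero; Cohen's d is undefined.")
  }
  (mean(y) - mean(x)) / sp
}

#' Classify an effect size by the conventional cutoffs
#'
#' @param d Cohen's d value(s); classification uses the magnitude.
#' @param thresholds Cutoff list from [effect_thresholds()].
#' @return Character vector: `"negligible"`, `"small"`, `"medium"` or
#'   `"large"`.
#' @export
#' @examples
#' classify_effect(c(0.1, 0.2, 0.5, -0.9))
classify_effect <- function(d, thresholds = effect_thresholds()) {
  cut_pts <- c(thresholds$small, thresholds$medium, thresholds$large)
  stopifnot(!is.unsorted(cut_pts))
  labels <- c("negligible", "small", "medium", "large")
  labels[1L + rowSums(outer(abs(d), cut_pts, `>=`))]
}

#' Linear model of effect size against error level
#'
#' Ordinary least squares of mean Cohen's d on the injected error
#' percentage: `d(x) = intercept + slope * x`. A positive slope expresses
#' the core degradation relationship — effect size grows linearly with
#' calibration-age error — and its inversion ([solve_threshold()]) locates
#' the tolerance threshold.
#'
#' @param levels Error levels in percent (>= 2 distinct values).
#' @param mean_d Mean Cohen's d at each level.
#' @return An `effect_size_model` with `slope`, `intercept`, `r_squared`
#'   and the fitted points.
#' @export
fit_effect_size_model <- function(levels, mean_d) {
  if (length(levels) != length(mean_d) || anyNA(levels) || anyNA(mean_d)) {
    stop_data("`levels` and `mean_d` must be equal-length and complete.")
  }
  if (length(unique(levels)) < 2L) {
    stop_data("At least 2 distinct error levels are needed to fit a line.")
  }
  fit <- lm(mean_d ~ levels)
  # suppressed: summary.lm warns on an exact (zero-residual) fit
  r2 <- suppressWarnings(summary(fit)$r.squared)
  effect_size_model(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]),
                    r_squared = r2,
                    data = tibble(level = levels, mean_d = mean_d))
}

#' Construct an effect-size model from known coefficients
#'
#' Useful for working with a previously reported model, e.g. one published
#' as `d(x) = (a x + b) / 100`.
#'
#' @param slope Change in d per percent of error.
#' @param intercept d at 0% error.
#' @param r_squared Optional fit quality.
#' @param data Optional tibble of the `(level, mean_d)` points fitted.
#' @return An `effect_size_model`.
#' @export
#' @examples
#' # a model published as d(x) = (1.2 x - 5.5) / 100
#' effect_size_model(slope = 1.2 / 100, intercept = -5.5 / 100)
effect_size_model <- function(slope, intercept, r_squared = NA_real_,
                              data = NULL) {
  check_number(slope, "slope")
  check_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, data = data),
            class = "effect_size_model")
}

#' @export
predict.effect_size_model <- function(object, levels, ...) {
  object$intercept + object$slope * levels
}

#' Invert the effect-size model at a target d
#'
#' Solves `d(x) = d_target` for the error percentage
#' `x = (d_target - intercept) / slope`. Only models with positive slope
#' have a crossing; both the real-valued solution and its nearest-integer
#' percent (half-up) are reported.
#'
#' @param model An `effect_size_model`.
#' @param d_target Effect size to solve for (default: the small-effect
#'   cutoff, 0.2).
#' @return One-row tibble: `d_target`, `level_exact`, `level_percent`.
#' @export
#' @examples
#' m <- effect_size_model(slope = 0.01, intercept = 0)
#' solve_threshold(m, 0.2)  # 20%
solve_threshold <- function(model, d_target = effect_thresholds()$small) {
  stopifnot(inherits(model, "effect_size_model"))
  check_number(d_target, "d_target")
  if (model$slope <= 0) {
    stop_data("Effect-size model slope is not positive; the target effect is never crossed.")
  }
  x <- (d_target - model$intercept) / model$slope
  tibble(d_target = d_target, level_exact = x,
         level_percent = as.integer(floor(x + 0.5)))
}

#' @export
print.effect_size_model <- function(x, ...) {
  cat("<effect_size_model> Cohen's d vs training-age error\n")
  cat(sprintf("  d(x) = (%.3f x %s %.3f) / 100",
              x$slope * 100, if (x$intercept < 0) "-" else "+",
              abs(x$intercept) * 100))
  if (!is.na(x$r_squared)) cat(sprintf("   (R^2 = %.3f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
tidy.effect_size_model <- function(x, ...) {
  tibble(term = c("(Intercept)", "level"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.effect_size_model <- function(x, ...) {
  tibble(r_squared = x$r_squared,
         n = if (is.null(x$data)) NA_integer_ else nrow(x$data))
}
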