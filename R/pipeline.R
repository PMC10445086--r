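# Orchestration of the calibration-error tolerance experiment:
#   1. split once into 70% calibration / 30% hold-out;
#   2. fit the baseline clock on exact calibration ages;
#   3. for each error level, repeatedly {inject fresh age error -> refit ->
#      evaluate on the SAME untouched hold-out partition};
#   4. per level, compare pooled per-sample hold-out errors against the
#      baseline's with t-tests and Cohen's d, locate first-crossing
#      thresholds, and fit the linear effect-size model.
# The hold-out partition and its ages are fixed for the whole sweep: only
# calibration ages are ever perturbed.

#' Configure an error sweep
#'
#' Defaults are desk-scale (levels every 5%, 5 repetitions) so a full sweep
#' runs in minutes on one core; the fine grid of the full experiment is
#' `sweep_config(levels = 1:100, repetitions = 10)`.
#'
#' @param levels Error levels in percent, each in `[0, 100]`.
#' @param repetitions Independent refits per level (>= 1); each draws fresh
#'   age noise (unless `redraw_per_rep = FALSE`) and fresh CV folds.
#' @param train_fraction Calibration fraction for the single initial split.
#' @param alpha_mix,cv_folds,nlambda Clock settings, see [fit_clock()].
#' @param seed Master seed; it deterministically spawns per-level,
#'   per-repetition child seeds, so the whole sweep is reproducible and
#'   levels are mutually independent.
#' @param redraw_per_rep If `FALSE`, age noise is drawn once per level and
#'   shared across repetitions (which then differ only in CV folds).
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(levels = seq(5, 100, by = 5), repetitions = 5L,
                         train_fraction = 0.7, alpha_mix = 0.5,
                         cv_folds = 10L, nlambda = 60L, seed = 1L,
                         redraw_per_rep = TRUE) {
  if (length(levels) < 1L || anyNA(levels) || any(levels < 0 | levels > 100)) {
    stop_config("`levels` must be percentages in [0, 100].")
  }
  if (anyDuplicated(levels)) stop_config("`levels` must be distinct.")
  check_number(repetitions, "repetitions", min = 1)
  check_number(train_fraction, "train_fraction")
  check_number(alpha_mix, "alpha_mix", min = 0, max = 1)
  check_number(cv_folds, "cv_folds", min = 3)
  check_seed(seed)
  structure(list(levels = as.numeric(levels),
                 repetitions = as.integer(repetitions),
                 train_fraction = train_fraction, alpha_mix = alpha_mix,
                 cv_folds = as.integer(cv_folds), nlambda = as.integer(nlambda),
                 seed = as.integer(seed),
                 redraw_per_rep = isTRUE(redraw_per_rep)),
            class = "sweep_config")
}

# One seed per purpose: split, baseline fit, then a (level x repetition) grid.
sweep_seed_plan <- function(config) {
  n_cells <- length(config$levels) * config$repetitions
  s <- spawn_seeds(config$seed, 2L + n_cells)
  list(split = s[1], baseline = s[2],
       cells = matrix(s[-(1:2)], nrow = length(config$levels),
                      ncol = config$repetitions))
}

#' Baseline performance of a clock on exact calibration ages
#'
#' Splits the dataset, fits the clock on unperturbed calibration ages and
#' evaluates it on the hold-out partition. This is the reference every
#' perturbed refit is compared against.
#'
#' @param dataset A `methyl_dataset`.
#' @param config A [sweep_config()].
#' @return A `performance_summary` for the hold-out samples.
#' @export
run_baseline <- function(dataset, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  plan <- sweep_seed_plan(config)
  parts <- split_train_test(dataset, config$train_fraction, seed = plan$split)
  model <- fit_clock(parts$train, alpha_mix = config$alpha_mix,
                     cv_folds = config$cv_folds, seed = plan$baseline,
                     nlambda = config$nlambda)
  pred <- predict_ages(model, parts$test)
  summarize_performance(pred, parts$test$ages, model)
}

#' Run the full error-injection sweep
#'
#' For every level in `config$levels`, runs `config$repetitions` independent
#' cycles of {perturb calibration ages -> refit clock -> evaluate on the
#' fixed hold-out partition}. Per-sample hold-out errors from all
#' repetitions of a level are pooled for the downstream tests.
#'
#' @param dataset A `methyl_dataset`.
#' @param config A [sweep_config()].
#' @param checkpoint_dir Optional directory: each completed level is written
#'   there as JSON and skipped (with a message) on a rerun, so interrupted
#'   100-level sweeps resume where they stopped. Results are identical with
#'   or without checkpointing because every cell's seed is precomputed.
#' @return A `sweep_result`: `baseline` (performance_summary), `summaries`
#'   (tibble: level, rep, seed, correlation, mean_absolute_error,
#'   mean_relative_error, n_selected_sites), `errors` (long tibble of
#'   per-sample hold-out errors: level, rep, sample_id, abs_error,
#'   rel_error), `test_ages`, and the config.
#' @export
run_error_sweep <- function(dataset, config = sweep_config(),
                            checkpoint_dir = NULL) {
  stopifnot(inherits(config, "sweep_config"))
  plan <- sweep_seed_plan(config)
  parts <- split_train_test(dataset, config$train_fraction, seed = plan$split)
  if (n_samples(parts$train) < config$cv_folds) {
    stop_config("Training partition is smaller than the number of CV folds.")
  }
  baseline_model <- fit_clock(parts$train, alpha_mix = config$alpha_mix,
                              cv_folds = config$cv_folds,
                              seed = plan$baseline, nlambda = config$nlambda)
  baseline <- summarize_performance(predict_ages(baseline_model, parts$test),
                                    parts$test$ages, baseline_model)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }

  run_level <- function(i) {
    level <- config$levels[i]
    ckpt <- if (is.null(checkpoint_dir)) NULL else
      file.path(checkpoint_dir, sprintf("level_%07.3f.json", level))
    if (!is.null(ckpt) && file.exists(ckpt)) {
      message(sprintf("Level %g%%: checkpoint found, skipping recomputation.", level))
      doc <- jsonlite::read_json(ckpt, simplifyVector = TRUE)
      return(list(summaries = as_tibble(doc$summaries),
                  errors = as_tibble(doc$errors)))
    }
    reps <- purrr::map(seq_len(config$repetitions), function(r) {
      cell_seed <- plan$cells[i, r]
      noise_seed <- if (config$redraw_per_rep) cell_seed else plan$cells[i, 1]
      perturbed <- inject_age_error(parts$train$ages, level, seed = noise_seed)
      model <- fit_clock(parts$train, ages = perturbed,
                         alpha_mix = config$alpha_mix,
                         cv_folds = config$cv_folds, seed = cell_seed,
                         nlambda = config$nlambda)
      perf <- summarize_performance(predict_ages(model, parts$test),
                                    parts$test$ages, model)
      list(summary = dplyr::bind_cols(tibble(level = level, rep = r,
                                             seed = cell_seed),
                                      tidy(perf)),
           errors = tibble(level = level, rep = r,
                           sample_id = names(parts$test$ages),
                           abs_error = unname(perf$per_sample_abs),
                           rel_error = unname(perf$per_sample_rel)))
    })
    out <- list(summaries = purrr::list_rbind(purrr::map(reps, "summary")),
                errors = purrr::list_rbind(purrr::map(reps, "errors")))
    if (!is.null(ckpt)) {
      jsonlite::write_json(out, ckpt, auto_unbox = FALSE, digits = NA,
                           dataframe = "columns")
    }
    out
  }

  per_level <- purrr::map(seq_along(config$levels), run_level)
  structure(list(
    baseline = baseline,
    summaries = purrr::list_rbind(purrr::map(per_level, "summaries")),
    errors = purrr::list_rbind(purrr::map(per_level, "errors")),
    test_ages = parts$test$ages,
    config = config),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d levels x %d repetitions, %d hold-out samples\n",
              length(x$config$levels), x$config$repetitions,
              length(x$test_ages)))
  cat("  baseline: ")
  print(x$baseline)
  invisible(x)
}

#' @export
tidy.sweep_result <- function(x, ...) x$summaries

# Pooled per-sample errors for one level of a sweep.
level_errors <- function(sweep, level, which = c("abs_error", "rel_error")) {
  which <- match.arg(which)
  sweep$errors[[which]][sweep$errors$level == level]
}

first_crossing <- function(levels, hit, sustained = 1L) {
  ok <- which(vapply(seq_along(hit), function(i) {
    j <- i:min(i + sustained - 1L, length(hit))
    length(j) == sustained && all(hit[j])
  }, logical(1)))
  if (length(ok) == 0L) NA_real_ else levels[ok[1]]
}

#' Locate the tolerance thresholds of a sweep
#'
#' Per level, the pooled per-sample hold-out errors are compared against the
#' baseline's with an unpaired t-test (absolute and relative errors) and
#' Cohen's d (absolute errors, positive when perturbation hurts). The
#' report gives the first level at which each criterion triggers —
#' `p < alpha` for either error type, `d` above the small-effect cutoff —
#' and the linear effect-size model fitted to the `(level, d)` points.
#'
#' @param sweep A `sweep_result`.
#' @param thresholds Cutoffs from [effect_thresholds()].
#' @param sustained Number of consecutive levels a criterion must hold to
#'   count as crossed (1 = plain first crossing; 3 guards against isolated
#'   noisy levels on fine grids).
#' @param var_equal Passed to [unpaired_t_test()].
#' @return A `threshold_report`: `per_level` (tibble: level, t_abs, p_abs,
#'   t_rel, p_rel, d, classification), `thresholds` (tibble: criterion,
#'   level — `NA` when never reached), and `effect_model`.
#' @export
detect_thresholds <- function(sweep, thresholds = effect_thresholds(),
                              sustained = 1L, var_equal = TRUE) {
  stopifnot(inherits(sweep, "sweep_result"))
  base_abs <- unname(sweep$baseline$per_sample_abs)
  base_rel <- unname(sweep$baseline$per_sample_rel)
  per_level <- purrr::list_rbind(purrr::map(sweep$config$levels, function(lv) {
    abs_err <- level_errors(sweep, lv, "abs_error")
    rel_err <- level_errors(sweep, lv, "rel_error")
    ht_abs <- unpaired_t_test(base_abs, abs_err, var_equal = var_equal)
    ht_rel <- unpaired_t_test(base_rel, rel_err, var_equal = var_equal)
    d_lv <- cohens_d(base_abs, abs_err)
    tibble(level = lv, t_abs = ht_abs$statistic, p_abs = ht_abs$p_value,
           t_rel = ht_rel$statistic, p_rel = ht_rel$p_value, d = d_lv,
           classification = classify_effect(d_lv, thresholds))
  }))
  per_level <- dplyr::arrange(per_level, .data$level)
  model <- if (nrow(per_level) >= 2L) {
    fit_effect_size_model(per_level$level, per_level$d)
  } else {
    NULL
  }
  report <- tibble(
    criterion = c("p_abs", "p_rel", "d_small"),
    level = c(first_crossing(per_level$level, per_level$p_abs < thresholds$alpha, sustained),
              first_crossing(per_level$level, per_level$p_rel < thresholds$alpha, sustained),
              first_crossing(per_level$level, per_level$d > thresholds$small, sustained)))
  structure(list(per_level = per_level, thresholds = report,
                 effect_model = model, alpha = thresholds$alpha,
                 d_small = thresholds$small, sustained = as.integer(sustained)),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  lv <- setNames(x$thresholds$level, x$thresholds$criterion)
  fmt <- function(v) if (is.na(v)) "not reached" else sprintf("%g%%", v)
  cat(sprintf("  absolute-error t-test first p < %.2f at: %s\n", x$alpha, fmt(lv[["p_abs"]])))
  cat(sprintf("  relative-error t-test first p < %.2f at: %s\n", x$alpha, fmt(lv[["p_rel"]])))
  cat(sprintf("  Cohen's d first above %.1f at:          %s\n", x$d_small, fmt(lv[["d_small"]])))
  if (!is.null(x$effect_model)) print(x$effect_model)
  invisible(x)
}

#' @export
tidy.threshold_report <- function(x, ...) x$per_level

#' Pool effect-size curves across datasets
#'
#' Averages the per-level Cohen's d curves of several sweeps (e.g. one per
#' species) and fits the linear effect-size model to the mean curve, the
#' cross-dataset summary from which a single tolerance threshold is read.
#'
#' @param reports List of `sweep_result` or `threshold_report` objects
#'   sharing the same level grid.
#' @param thresholds Cutoffs used when `reports` contains raw sweeps.
#' @return List with `mean_d` (tibble: level, mean_d) and `model` (an
#'   `effect_size_model` fitted to the means).
#' @export
aggregate_datasets <- function(reports, thresholds = effect_thresholds()) {
  if (!is.list(reports) || length(reports) == 0L) {
    stop_config("`reports` must be a non-empty list of sweeps or threshold reports.")
  }
  curves <- purrr::map(reports, function(r) {
    if (inherits(r, "sweep_result")) r <- detect_thresholds(r, thresholds)
    stopifnot(inherits(r, "threshold_report"))
    r$per_level[, c("level", "d")]
  })
  grid <- curves[[1]]$level
  for (cv in curves[-1]) {
    if (!identical(cv$level, grid)) {
      stop_data("All datasets must be swept on the same level grid to aggregate.")
    }
  }
  mean_d <- tibble(level = grid,
                   mean_d = rowMeans(do.call(cbind, purrr::map(curves, "d"))))
  list(mean_d = mean_d,
       model = fit_effect_size_model(mean_d$level, mean_d$mean_d))
}

#' Sweep a random subsample of a dataset
#'
#' Draws `target_n` samples without replacement (seeded by the config's
#' master seed) and runs the full error sweep on the subset — the
#' experiment that asks whether the tolerance threshold depends on cohort
#' size. `target_n` equal to the dataset size leaves the dataset untouched,
#' so the result coincides with the plain sweep.
#'
#' @param dataset A `methyl_dataset`.
#' @param target_n Number of samples to keep.
#' @param config A [sweep_config()].
#' @param checkpoint_dir Passed to [run_error_sweep()].
#' @return A `sweep_result` for the subsample; the drawn sample ids are in
#'   `attr(, "subsample_ids")`.
#' @export
subsample_experiment <- function(dataset, target_n, config = sweep_config(),
                                 checkpoint_dir = NULL) {
  validate_dataset(dataset)
  check_number(target_n, "target_n", min = 1)
  n <- n_samples(dataset)
  if (target_n > n) {
    stop_config(sprintf("Cannot subsample %d from %d samples.", target_n, n))
  }
  min_viable <- ceiling((config$cv_folds + 1) / config$train_fraction)
  if (target_n < min_viable) {
    stop_config(sprintf(
      "target_n = %d is below the minimum viable cohort (%d) for a %d-fold fit after the split.",
      target_n, min_viable, config$cv_folds))
  }
  sub <- if (target_n == n) dataset else {
    idx <- withr::with_seed(config$seed, sort(sample.int(n, target_n)))
    subset_samples(dataset, idx)
  }
  res <- run_error_sweep(sub, config, checkpoint_dir = checkpoint_dir)
  attr(res, "subsample_ids") <- names(sub$ages)
  res
}
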