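# Elastic-net epigenetic clocks. A clock is a sparse linear predictor of
# chronological age from CpG beta values: age ~ intercept + sum_j w_j * beta_j.
# Calibration follows common epigenetic-clock practice: elastic net with the
# mixing parameter alpha = 0.5 (equal L1/L2 weight, inducing sparse site
# selection), penalty strength chosen by internal k-fold cross-validation
# minimising mean squared prediction error. Site selection is data-driven on
# every fit: a refit under perturbed ages is free to pick a different site set.

#' Split a dataset into calibration and hold-out partitions
#'
#' Samples are assigned at random: `round(n * train_fraction)` (half-up) to
#' the training partition, the rest to testing. The two partitions are
#' disjoint and exhaustive.
#'
#' @param dataset A `methyl_dataset`.
#' @param train_fraction Proportion of samples used for calibration
#'   (default 0.7, i.e. a 70/30 split).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with elements `train` and `test`, both `methyl_dataset`s.
#' @export
split_train_test <- function(dataset, train_fraction = 0.7, seed = NULL) {
  validate_dataset(dataset)
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_config("`train_fraction` must be strictly between 0 and 1.")
  }
  check_seed(seed)
  n <- n_samples(dataset)
  n_train <- floor(n * train_fraction + 0.5)  # round half up, fixed for reproducibility
  if (n_train < 1L || n_train >= n) {
    stop_config(sprintf("Split of %d samples at fraction %.2f leaves an empty partition.",
                        n, train_fraction))
  }
  idx <- with_seed_or_rng(seed, sample.int(n, n_train))
  list(train = subset_samples(dataset, sort(idx)),
       test = subset_samples(dataset, sort(setdiff(seq_len(n), idx))))
}

#' Calibrate an elastic-net age clock
#'
#' Fits `age ~ betas` by elastic-net regression with mixing parameter
#' `alpha_mix` (default 0.5). The penalty strength lambda is chosen by
#' `cv_folds`-fold cross-validation on the training samples, taking the
#' lambda that minimises mean squared prediction error. Features are
#' standardised internally; coefficients are reported on the original beta
#' scale. Sites with nonzero coefficients are the clock's selected sites.
#'
#' `ages` overrides the dataset's own ages, which is how perturbed
#' (error-injected) calibration ages enter a fit while the dataset keeps the
#' truth.
#'
#' @param train A `methyl_dataset` of calibration samples.
#' @param ages Optional numeric vector of calibration ages to fit against
#'   (defaults to `train$ages`).
#' @param alpha_mix Elastic-net mixing parameter in `[0, 1]`; 0.5 weights
#'   the absolute-value and squared penalties equally.
#' @param cv_folds Folds for the internal lambda cross-validation.
#' @param seed Integer seed controlling fold assignment.
#' @param nlambda Length of the log-spaced candidate lambda path. The
#'   CV-minimising lambda sits well inside the path on age-clock data, so
#'   60 points resolve it as finely as glmnet's 100 default while skipping
#'   the slow dense tail of near-zero penalties.
#' @param lambda Optional fixed penalty strength. When given, the internal
#'   cross-validation is skipped and the clock is extracted from the
#'   regularisation path at this lambda — useful for studying how site
#'   selection responds to the penalty.
#' @return A `clock_model`: intercept, named vector `weights` of nonzero
#'   coefficients, `alpha_mix`, chosen `lambda`, and training metadata.
#' @export
fit_clock <- function(train, ages = NULL, alpha_mix = 0.5, cv_folds = 10L,
                      seed = NULL, nlambda = 60L, lambda = NULL) {
  validate_dataset(train)
  if (is.null(ages)) ages <- train$ages
  n <- n_samples(train)
  if (length(ages) != n || anyNA(ages)) {
    stop_data("`ages` must supply one non-missing age per training sample.")
  }
  check_number(alpha_mix, "alpha_mix", min = 0, max = 1)
  check_number(cv_folds, "cv_folds", min = 3)
  check_seed(seed)
  if (n < cv_folds) {
    stop_config(sprintf("%d training samples cannot support %d-fold cross-validation.",
                        n, cv_folds))
  }
  if (sd(ages) == 0) {
    stop_data("Calibration ages are constant; an age clock cannot be fit.")
  }

  x <- t(train$betas)
  variable <- apply(x, 2L, function(col) any(col != col[1]))
  meta <- list(seed = seed, n_train = n, cv_folds = as.integer(cv_folds))

  if (!any(variable)) {
    warn("All CpG sites are constant; returning an intercept-only clock predicting the mean calibration age.")
    return(new_clock_model(mean(ages), setNames(numeric(0), character(0)),
                           alpha_mix, NA_real_, meta))
  }

  if (sum(variable) == 1L) {
    # glmnet needs >= 2 predictors; a single usable site reduces to OLS.
    site <- colnames(x)[variable]
    fit <- lm(ages ~ x[, site])
    w <- setNames(coef(fit)[2], site)
    return(new_clock_model(unname(coef(fit)[1]), w[w != 0], alpha_mix, 0, meta))
  }

  if (!is.null(lambda)) {
    check_number(lambda, "lambda", min = 0)
    path <- glmnet::glmnet(x, ages, alpha = alpha_mix,
                           nlambda = as.integer(nlambda), family = "gaussian")
    co <- coef(path, s = lambda)
    chosen <- lambda
  } else {
    cv <- with_seed_or_rng(seed,
      glmnet::cv.glmnet(x, ages, alpha = alpha_mix, nfolds = as.integer(cv_folds),
                        nlambda = as.integer(nlambda), family = "gaussian"))
    co <- coef(cv, s = "lambda.min")
    chosen <- cv$lambda.min
  }
  w <- setNames(as.numeric(co)[-1], rownames(co)[-1])
  w <- w[w != 0]
  new_clock_model(as.numeric(co)[1], w, alpha_mix, chosen, meta)
}

new_clock_model <- function(intercept, weights, alpha_mix, lambda, meta) {
  structure(list(intercept = intercept, weights = weights,
                 alpha_mix = alpha_mix, lambda = lambda,
                 training_meta = meta),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> elastic net (alpha = %.2f), %d selected CpG sites\n",
              x$alpha_mix, count_selected_sites(x)))
  cat(sprintf("  intercept %.3f, lambda %.4g, trained on %d samples\n",
              x$intercept, x$lambda, x$training_meta$n_train))
  invisible(x)
}

#' Predict ages with a fitted clock
#'
#' Applies the linear form `intercept + sum_j weight_j * beta_ij` to each
#' sample. Predictions are reported raw: a negative predicted age is
#' flagged with a warning but never clamped, so downstream error metrics
#' are not silently biased.
#'
#' @param model A `clock_model`.
#' @param dataset A `methyl_dataset` containing every selected site.
#' @return Numeric vector of predicted ages, named by sample.
#' @export
predict_ages <- function(model, dataset) {
  stopifnot(inherits(model, "clock_model"))
  validate_dataset(dataset)
  w <- model$weights
  if (length(w) == 0L) {
    pred <- setNames(rep(model$intercept, n_samples(dataset)),
                     colnames(dataset$betas))
    return(pred)
  }
  missing <- setdiff(names(w), rownames(dataset$betas))
  if (length(missing) > 0L) {
    stop_data(sprintf("Dataset is missing %d site(s) required by the clock: %s",
                      length(missing),
                      paste(head(missing, 5L), collapse = ", ")))
  }
  pred <- model$intercept +
    drop(crossprod(dataset$betas[names(w), , drop = FALSE], w))
  if (any(pred < 0)) {
    warn(sprintf("%d predicted age(s) are negative; reported unclamped.",
                 sum(pred < 0)))
  }
  pred
}

#' Number of CpG sites selected by a clock
#'
#' @param model A `clock_model`.
#' @return Count of strictly nonzero coefficients.
#' @export
count_selected_sites <- function(model) {
  stopifnot(inherits(model, "clock_model"))
  sum(model$weights != 0)
}

#' Shared selected sites between two clocks
#'
#' Refitting a clock after perturbing calibration ages typically changes
#' which sites carry nonzero weight; this counts the overlap.
#'
#' @param model_a,model_b Fitted `clock_model`s.
#' @return Number of sites selected by both.
#' @export
selection_overlap <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "clock_model"), inherits(model_b, "clock_model"))
  length(intersect(names(model_a$weights)[model_a$weights != 0],
                   names(model_b$weights)[model_b$weights != 0]))
}

#' Iteratively drop outlier calibration samples and refit
#'
#' Fits a clock, flags training samples whose absolute residual exceeds
#' `k_sd` residual standard deviations, removes them, and refits; the cycle
#' repeats until no sample is flagged or `max_iter` rounds have run. This is
#' the screening loop a clock developer can use when some calibration ages
#' are suspected of carrying large errors.
#'
#' @param train A `methyl_dataset` of calibration samples.
#' @param k_sd Residual-SD multiple beyond which a sample is an outlier.
#' @param max_iter Maximum pruning rounds; 0 returns the baseline fit.
#' @param alpha_mix,cv_folds,seed Passed to [fit_clock()].
#' @return List with `model` (the final `clock_model`) and `removed`
#'   (character vector of dropped sample ids, in removal order).
#' @export
prune_outliers_and_refit <- function(train, k_sd = 3, max_iter = 5L,
                                     alpha_mix = 0.5, cv_folds = 10L,
                                     seed = NULL) {
  check_number(k_sd, "k_sd")
  if (k_sd <= 0) stop_config("`k_sd` must be positive.")
  check_number(max_iter, "max_iter", min = 0)
  seeds <- if (is.null(seed)) rep(list(NULL), max_iter + 1) else
    as.list(spawn_seeds(seed, max_iter + 1))
  current <- train
  model <- fit_clock(current, alpha_mix = alpha_mix, cv_folds = cv_folds,
                     seed = seeds[[1]])
  removed <- character(0)
  iter <- 0L
  while (iter < max_iter) {
    resid <- predict_ages(model, current) - current$ages
    s <- sd(resid)
    if (is.na(s) || s == 0) break
    out <- abs(resid) > k_sd * s
    if (!any(out)) break
    keep <- which(!out)
    if (length(keep) < model$training_meta$cv_folds) {
      warn("Pruning stopped: removing flagged outliers would leave too few samples for cross-validation.")
      break
    }
    removed <- c(removed, names(current$ages)[out])
    current <- subset_samples(current, keep)
    iter <- iter + 1L
    model <- fit_clock(current, alpha_mix = alpha_mix, cv_folds = cv_folds,
                       seed = seeds[[iter + 1L]])
  }
  list(model = model, removed = removed)
}

#' Serialise a clock to JSON / restore it
#'
#' The document stores the intercept, the site-to-weight map, the mixing
#' parameter, the chosen penalty strength and training metadata, so a fitted
#' clock can be audited or reapplied without the training data.
#'
#' @param model A `clock_model`.
#' @param path JSON file path.
#' @return `write_clock()` returns `path` invisibly; `read_clock()` returns
#'   a `clock_model`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  doc <- list(
    format = "clocktol_clock", version = as.character(packageVersion("clocktol")),
    intercept = model$intercept,
    weights = as.list(model$weights),
    alpha_mix = model$alpha_mix,
    lambda = model$lambda,
    training_meta = model$training_meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("Clock file not found: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "clocktol_clock")) {
    stop_data(sprintf("'%s' is not a serialised clock.", path))
  }
  w <- unlist(doc$weights)
  if (is.null(w)) w <- setNames(numeric(0), character(0))
  meta <- doc$training_meta
  meta$seed <- if (is.null(meta$seed)) NULL else as.integer(meta$seed)
  new_clock_model(doc$intercept, w, doc$alpha_mix,
                  if (is.null(doc$lambda)) NA_real_ else doc$lambda, meta)
}

#' @export
tidy.clock_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$weights)),
         estimate = c(x$intercept, unname(x$weights)))
}

#' @export
glance.clock_model <- function(x, ...) {
  tibble(n_selected = count_selected_sites(x),
         alpha_mix = x$alpha_mix,
         lambda = x$lambda,
         n_train = x$training_meta$n_train,
         cv_folds = x$training_meta$cv_folds)
}
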