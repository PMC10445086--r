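# Fixtures are built in code: a small, fast cohort for unit tests and the
# standard study-scale cohort used by the end-to-end checks.

# 60 samples, 30 informative + 120 noise sites: fits in well under a second
# per clock while keeping a clear age signal.
tiny_dataset <- function(seed = 1, n = 60, noise_sd = 0.03) {
  generate_dataset(
    dataset_profile("tiny", n_samples = n, age_min = 4, age_max = 40),
    signal_spec(n_informative = 30, n_noise = 120, noise_sd = noise_sd),
    seed = seed)
}

# Study-scale synthetic cohort: 150 samples over a human-like adult age
# range with the default signal (100 informative + 900 noise sites).
study_dataset <- function(seed = 1, n = 150) {
  generate_dataset(
    dataset_profile("study", n_samples = n, age_min = 16, age_max = 88),
    signal_spec(), seed = seed)
}

# Noise-free cohort whose baselines stay clear of the [0, 1] clamp, so the
# age signal is exactly linear and recoverable.
noiseless_dataset <- function(seed = 1, n = 200, n_informative = 50) {
  generate_dataset(
    dataset_profile("clean", n_samples = n, age_min = 10, age_max = 50),
    signal_spec(n_informative = n_informative, n_noise = 150,
                slope_magnitude = 0.4, noise_sd = 0,
                baseline_range = c(0.45, 0.55)),
    seed = seed)
}

# Pooled two-sample t statistic, written from the textbook formula so it is
# independent of the implementation under test.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Exhaustive two-sided permutation p-value for the pooled t statistic.
oracle_permutation_p <- function(x, y) {
  z <- c(x, y)
  idx <- utils::combn(length(z), length(x))
  t_obs <- abs(oracle_pooled_t(x, y))
  t_all <- apply(idx, 2, function(i) abs(oracle_pooled_t(z[i], z[-i])))
  mean(t_all >= t_obs - 1e-12)
}

# Hand-built sparse clock for tests that need known coefficients.
manual_clock <- function(intercept, weights) {
  clocktol:::new_clock_model(intercept, weights, alpha_mix = 0.5,
                             lambda = NA_real_,
                             meta = list(seed = NULL, n_train = NA_integer_,
                                         cv_folds = NA_integer_))
}

# Minimal threshold_report carrying a chosen per-level d curve, for
# aggregation tests that need exact curves.
manual_report <- function(levels, d) {
  structure(list(per_level = tibble::tibble(level = levels, d = d)),
            class = "threshold_report")
}
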