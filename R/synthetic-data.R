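# Synthetic methylation datasets with a known age signal. These stand in for
# the public known-age datasets an epigenetic-clock study would download: a
# minority of CpG sites whose beta value drifts linearly with age (up or
# down), a majority of age-uninformative sites, Gaussian measurement noise,
# and betas clamped to the unit interval.

.profile_presets <- tibble::tribble(
  ~name,        ~n_samples, ~age_min, ~age_max, ~age_unit,
  "human",      394L,       16,       88,       "years",
  "zebrafish",  96L,        11.9,     60.1,     "weeks",
  "mouse",      153L,       1,        31,       "weeks",
  "turtle",     63L,        1,        43,       "years"
)

#' Built-in dataset profiles
#'
#' The four profiles mirror the known-age methylation cohorts commonly used
#' to calibrate vertebrate epigenetic clocks: human whole blood (n = 394,
#' ages 16-88 years), zebrafish caudal fin (n = 96, 11.9-60.1 weeks), mouse
#' multi-tissue (n = 153, 1-31 weeks) and green sea turtle skin (n = 63,
#' 1-43 years).
#'
#' @return A tibble with columns `name`, `n_samples`, `age_min`, `age_max`,
#'   `age_unit`.
#' @export
#' @examples
#' profile_presets()
profile_presets <- function() .profile_presets

#' Describe a methylation cohort to simulate
#'
#' A profile fixes the sampling frame of a synthetic dataset: how many
#' animals and the chronological-age range they span. Pass one of the preset
#' names (see [profile_presets()]) or give the fields explicitly.
#'
#' @param name Preset name (`"human"`, `"zebrafish"`, `"mouse"`, `"turtle"`)
#'   or a label for a custom profile.
#' @param n_samples Number of samples (>= 10).
#' @param age_min,age_max Age range bounds; `0 < age_min < age_max`.
#' @param age_unit Unit label, `"years"` or `"weeks"`.
#' @return A `dataset_profile` list.
#' @export
#' @examples
#' dataset_profile("turtle")
#' dataset_profile("pilot", n_samples = 40, age_min = 2, age_max = 20)
dataset_profile <- function(name, n_samples = NULL, age_min = NULL,
                            age_max = NULL, age_unit = "years") {
  if (!is.character(name) || length(name) != 1L) {
    stop_config("`name` must be a single string.")
  }
  preset <- .profile_presets[.profile_presets$name == name, ]
  if (is.null(n_samples) && is.null(age_min) && is.null(age_max)) {
    if (nrow(preset) == 0L) {
      stop_config(sprintf(
        "Unknown profile '%s'. Valid presets: %s. For a custom profile give n_samples, age_min and age_max.",
        name, paste(.profile_presets$name, collapse = ", ")))
    }
    n_samples <- preset$n_samples
    age_min <- preset$age_min
    age_max <- preset$age_max
    age_unit <- preset$age_unit
  }
  check_number(n_samples, "n_samples", min = 10)
  check_number(age_min, "age_min")
  check_number(age_max, "age_max")
  if (!(age_min > 0 && age_max > age_min)) {
    stop_config("Profile requires 0 < age_min < age_max.")
  }
  if (!age_unit %in% c("years", "weeks")) {
    stop_config("`age_unit` must be 'years' or 'weeks'.")
  }
  structure(list(name = name, n_samples = as.integer(n_samples),
                 age_min = age_min, age_max = age_max, age_unit = age_unit),
            class = "dataset_profile")
}

#' Describe the age signal written into synthetic CpG sites
#'
#' Informative sites change linearly in min-max-normalised age by
#' `slope_magnitude` beta units over the profile's full age range, a
#' `direction_mix` fraction of them increasing with age and the rest
#' decreasing. All sites get i.i.d. Gaussian noise on the beta scale and are
#' clamped to `[0, 1]`.
#'
#' @param n_informative Number of age-informative sites (>= 1).
#' @param n_noise Number of age-uninformative sites.
#' @param slope_magnitude Absolute beta change across the age range.
#' @param direction_mix Fraction of informative sites that increase with age.
#' @param noise_sd Beta-scale standard deviation of the measurement noise.
#' @param baseline_range Interval within `[0, 1]` from which site intercepts
#'   (beta at `age_min`) are drawn uniformly.
#' @return A `signal_spec` list.
#' @export
signal_spec <- function(n_informative = 100L, n_noise = 900L,
                        slope_magnitude = 0.4, direction_mix = 0.5,
                        noise_sd = 0.05, baseline_range = c(0.15, 0.85)) {
  check_number(n_informative, "n_informative", min = 0)
  check_number(n_noise, "n_noise", min = 0)
  if (n_informative < 1) {
    stop_config("`n_informative` must be >= 1: a dataset with no age signal cannot calibrate a clock.")
  }
  check_number(slope_magnitude, "slope_magnitude", min = 0)
  check_number(direction_mix, "direction_mix", min = 0, max = 1)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(baseline_range, "baseline_range", min = 0, max = 1, len = 2L)
  if (baseline_range[1] > baseline_range[2]) {
    stop_config("`baseline_range` must be increasing.")
  }
  structure(list(n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 slope_magnitude = slope_magnitude,
                 direction_mix = direction_mix,
                 noise_sd = noise_sd,
                 baseline_range = baseline_range),
            class = "signal_spec")
}

#' Draw chronological ages for a profile
#'
#' Ages are sampled uniformly over the profile's range; the presets carry no
#' information about the real cohorts' age distributions beyond the range,
#' so the flat distribution is the least-structured choice covering it.
#'
#' @param profile A [dataset_profile()].
#' @param seed Integer seed for reproducibility (NULL uses the current RNG).
#' @return Numeric vector of `n_samples` ages in profile units.
#' @export
generate_ages <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "dataset_profile"))
  check_seed(seed)
  with_seed_or_rng(seed,
    runif(profile$n_samples, profile$age_min, profile$age_max))
}

#' Simulate a methylation dataset with known age structure
#'
#' Informative site j has
#' `beta_ij = clamp(b0_j + s_j * z_i + e_ij, 0, 1)` where `z_i` is the
#' sample's age min-max-normalised to `[0, 1]`, `s_j = +/- slope_magnitude`
#' (sign per `direction_mix`), `b0_j` is a uniform draw from
#' `baseline_range`, and `e_ij ~ N(0, noise_sd)`. Noise sites omit the age
#' term. The generated object records which sites carry signal
#' (`site_info`), ground truth that tests and demonstrations can use but the
#' clock never sees.
#'
#' @param profile A [dataset_profile()].
#' @param signal A [signal_spec()].
#' @param seed Integer seed; the dataset is bit-identical under a fixed seed.
#' @return A `methyl_dataset`: list with `betas` (site x sample matrix),
#'   `ages` (named numeric), `age_unit`, `site_info` (tibble: site_id,
#'   informative, slope) and `profile_name`.
#' @export
#' @examples
#' d <- generate_dataset(dataset_profile("turtle"), signal_spec(20, 80), seed = 1)
#' d
generate_dataset <- function(profile, signal = signal_spec(), seed = NULL) {
  stopifnot(inherits(profile, "dataset_profile"), inherits(signal, "signal_spec"))
  check_seed(seed)
  n <- profile$n_samples
  p_inf <- signal$n_informative
  p_noise <- signal$n_noise
  p <- p_inf + p_noise
  if (p < 1L) stop_config("Signal must define at least one site.")

  with_seed_or_rng(seed, {
    ages <- runif(n, profile$age_min, profile$age_max)
    z <- (ages - profile$age_min) / (profile$age_max - profile$age_min)
    n_up <- round(signal$direction_mix * p_inf)
    slopes <- c(sample(rep(c(1, -1), c(n_up, p_inf - n_up))) * signal$slope_magnitude,
                rep(0, p_noise))
    b0 <- runif(p, signal$baseline_range[1], signal$baseline_range[2])
    eps <- if (signal$noise_sd > 0) {
      matrix(rnorm(p * n, 0, signal$noise_sd), p, n)
    } else {
      matrix(0, p, n)
    }
    betas <- b0 + outer(slopes, z) + eps
  })
  betas <- pmin(pmax(betas, 0), 1)

  site_ids <- sprintf("cpg_%05d", seq_len(p))
  sample_ids <- sprintf("s%04d", seq_len(n))
  dimnames(betas) <- list(site_ids, sample_ids)
  names(ages) <- sample_ids

  new_methyl_dataset(
    betas = betas, ages = ages, age_unit = profile$age_unit,
    site_info = tibble(site_id = site_ids,
                       informative = slopes != 0,
                       slope = slopes),
    profile_name = profile$name)
}

new_methyl_dataset <- function(betas, ages, age_unit = "years",
                               site_info = NULL, profile_name = NA_character_) {
  structure(list(betas = betas, ages = ages, age_unit = age_unit,
                 site_info = site_info, profile_name = profile_name),
            class = "methyl_dataset")
}

#' Assemble a methylation dataset from a beta matrix and ages
#'
#' @param betas Numeric site x sample matrix with row and column names,
#'   values in `[0, 1]`.
#' @param ages Numeric vector of positive ages, one per sample (same order
#'   as the matrix columns, or named by sample id).
#' @param age_unit Unit label carried through reports.
#' @return A `methyl_dataset`.
#' @export
methyl_dataset <- function(betas, ages, age_unit = "years") {
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop_data("`betas` must be a numeric matrix (sites x samples).")
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop_data("`betas` needs site row names and sample column names.")
  }
  if (!is.null(names(ages))) ages <- ages[colnames(betas)]
  if (length(ages) != ncol(betas) || anyNA(ages)) {
    stop_data("`ages` must supply one non-missing age per sample.")
  }
  names(ages) <- colnames(betas)
  d <- new_methyl_dataset(betas, ages, age_unit)
  validate_dataset(d)
  d
}

validate_dataset <- function(d) {
  b <- d$betas
  if (anyNA(b) || !is.numeric(b)) {
    bad <- which(is.na(b), arr.ind = TRUE)[1, , drop = TRUE]
    stop_data(sprintf("Non-numeric or missing beta at site '%s', sample '%s'.",
                      rownames(b)[bad[1]], colnames(b)[bad[2]]))
  }
  out <- which(b < 0 | b > 1, arr.ind = TRUE)
  if (nrow(out) > 0L) {
    stop_data(sprintf("Beta value %.4g outside [0, 1] at site '%s', sample '%s'.",
                      b[out[1, 1], out[1, 2]],
                      rownames(b)[out[1, 1]], colnames(b)[out[1, 2]]))
  }
  if (anyDuplicated(rownames(b))) {
    stop_data(sprintf("Duplicated site id '%s'.",
                      rownames(b)[duplicated(rownames(b))][1]))
  }
  if (anyDuplicated(colnames(b))) {
    stop_data(sprintf("Duplicated sample id '%s'.",
                      colnames(b)[duplicated(colnames(b))][1]))
  }
  if (length(d$ages) != ncol(b) || anyNA(d$ages)) {
    stop_data("Every sample needs a non-missing age.")
  }
  if (any(d$ages <= 0)) {
    stop_data(sprintf("Non-positive age for sample '%s': relative error is undefined at age <= 0.",
                      names(d$ages)[d$ages <= 0][1]))
  }
  invisible(d)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("<methyl_dataset> %d CpG sites x %d samples\n",
              nrow(x$betas), ncol(x$betas)))
  cat(sprintf("  ages: %.3g-%.3g %s", min(x$ages), max(x$ages), x$age_unit))
  if (!is.na(x$profile_name)) cat(sprintf("  (profile '%s')", x$profile_name))
  cat("\n")
  if (!is.null(x$site_info)) {
    cat(sprintf("  signal: %d informative, %d noise sites\n",
                sum(x$site_info$informative), sum(!x$site_info$informative)))
  }
  invisible(x)
}

n_samples <- function(d) ncol(d$betas)
n_sites <- function(d) nrow(d$betas)

# Column subset preserving ages and metadata.
subset_samples <- function(d, idx) {
  new_methyl_dataset(d$betas[, idx, drop = FALSE], d$ages[idx],
                     d$age_unit, d$site_info, d$profile_name)
}

#' Write / read a methylation dataset as plain text
#'
#' The on-disk form mirrors a GEO-style series matrix: a TSV with one row
#' per CpG site (first column `site_id`, remaining columns samples) plus a
#' CSV of per-sample metadata (`sample_id`, `age`, `age_unit`). Betas are
#' written at round-trip precision, so write followed by read reproduces
#' the dataset exactly.
#'
#' @param dataset A `methyl_dataset`.
#' @param betas_path Path of the beta-matrix TSV.
#' @param samples_path Path of the sample-metadata CSV.
#' @return `write_dataset()` returns the two paths invisibly;
#'   `read_dataset()` returns a validated `methyl_dataset`.
#' @export
write_dataset <- function(dataset, betas_path, samples_path) {
  validate_dataset(dataset)
  # 17 significant digits round-trip IEEE doubles exactly
  chr <- apply(dataset$betas, 2L, function(col) sprintf("%.17g", col))
  mat <- dplyr::bind_cols(tibble(site_id = rownames(dataset$betas)),
                          tibble::as_tibble(chr))
  readr::write_tsv(mat, betas_path)
  meta <- tibble(sample_id = names(dataset$ages),
                 age = sprintf("%.17g", unname(dataset$ages)),
                 age_unit = dataset$age_unit)
  readr::write_csv(meta, samples_path)
  invisible(c(betas = betas_path, samples = samples_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(betas_path, samples_path) {
  if (!file.exists(betas_path)) stop_data(sprintf("Beta matrix file not found: %s", betas_path))
  if (!file.exists(samples_path)) stop_data(sprintf("Sample metadata file not found: %s", samples_path))
  # columns come in as text and are converted with as.numeric(), which is
  # correctly rounded, so a 17-digit write/read cycle is lossless
  mat <- readr::read_tsv(betas_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"site_id" %in% names(mat)) {
    stop_data("Beta matrix must have a 'site_id' first column.")
  }
  chr <- as.matrix(mat[, setdiff(names(mat), "site_id"), drop = FALSE])
  betas <- suppressWarnings(matrix(as.numeric(chr), nrow(chr), ncol(chr),
                                   dimnames = list(mat$site_id, colnames(chr))))
  meta <- readr::read_csv(samples_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  if ("age" %in% names(meta)) {
    meta$age <- suppressWarnings(as.numeric(meta$age))
  }
  if (!all(c("sample_id", "age") %in% names(meta))) {
    stop_data("Sample metadata must have 'sample_id' and 'age' columns.")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop_data(sprintf("Duplicated sample id '%s' in metadata.",
                      meta$sample_id[duplicated(meta$sample_id)][1]))
  }
  missing <- setdiff(colnames(betas), meta$sample_id)
  if (length(missing) > 0L) {
    stop_data(sprintf("No age recorded for sample '%s'.", missing[1]))
  }
  ages <- setNames(meta$age, meta$sample_id)[colnames(betas)]
  unit <- if ("age_unit" %in% names(meta)) meta$age_unit[1] else "years"
  d <- new_methyl_dataset(betas, ages, unit)
  validate_dataset(d)
  d
}
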