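test_that("profiles validate their fields and expose the four presets", {
  presets <- profile_presets()
  expect_setequal(presets$name, c("human", "zebrafish", "mouse", "turtle"))
  expect_equal(presets$n_samples, c(394L, 96L, 153L, 63L))

  p <- dataset_profile("human")
  expect_equal(p$n_samples, 394L)
  expect_equal(c(p$age_min, p$age_max), c(16, 88))

  expect_error(dataset_profile("axolotl"), class = "clocktol_config_error")
  expect_error(dataset_profile("x", n_samples = 5, age_min = 1, age_max = 2),
               class = "clocktol_config_error")
  expect_error(dataset_profile("x", n_samples = 20, age_min = 5, age_max = 5),
               class = "clocktol_config_error")
  expect_error(dataset_profile("x", n_samples = 20, age_min = -1, age_max = 5),
               class = "clocktol_config_error")
})

test_that("generated ages cover the profile range and are seeded", {
  # degenerate range: all ages pinned at ~10
  eps <- 1e-9
  p <- dataset_profile("pin", n_samples = 10, age_min = 10, age_max = 10 + eps)
  expect_equal(generate_ages(p, seed = 1), rep(10, 10), tolerance = 1e-6)

  human <- generate_ages(dataset_profile("human"), seed = 3)
  expect_length(human, 394)
  expect_true(all(human >= 16 & human <= 88))

  expect_identical(generate_ages(dataset_profile("turtle"), seed = 5),
                   generate_ages(dataset_profile("turtle"), seed = 5))

  # uniform-mean oracle: mean of U(1, 43) is 22 with SE (43-1)/sqrt(12n)
  big <- generate_ages(dataset_profile("big", n_samples = 10000,
                                       age_min = 1, age_max = 43), seed = 7)
  se <- (43 - 1) / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(big) - 22), 3 * se)
})

test_that("signal spec rejects degenerate configurations", {
  expect_error(signal_spec(n_informative = 0), class = "clocktol_config_error")
  expect_error(signal_spec(direction_mix = 1.5), class = "clocktol_config_error")
  expect_error(signal_spec(noise_sd = -0.1), class = "clocktol_config_error")
  expect_error(signal_spec(baseline_range = c(0.9, 0.1)),
               class = "clocktol_config_error")
})

test_that("noiseless informative sites are exactly monotone in age", {
  prof <- dataset_profile("mono", n_samples = 50, age_min = 2, age_max = 20)
  sig <- signal_spec(n_informative = 1, n_noise = 3, slope_magnitude = 0.5,
                     direction_mix = 1, noise_sd = 0,
                     baseline_range = c(0.2, 0.4))
  d <- generate_dataset(prof, sig, seed = 2)
  site <- d$site_info$site_id[d$site_info$informative]
  ord <- order(d$ages)
  expect_true(all(diff(d$betas[site, ord]) >= 0))
  # and perfectly correlated with age when the clamp is never hit
  expect_equal(cor(d$betas[site, ], d$ages), 1)
})

test_that("betas stay in [0, 1] and datasets are bit-identical under a seed", {
  for (s in 1:5) {
    prof <- dataset_profile("rand", n_samples = 10 + 5 * s,
                            age_min = s, age_max = 10 * s + 20)
    sig <- signal_spec(n_informative = 3 * s, n_noise = 10,
                       slope_magnitude = 0.2 * s, noise_sd = 0.05 * s,
                       direction_mix = 0.3,
                       baseline_range = c(0.05, 0.95))
    d <- generate_dataset(prof, sig, seed = s)
    expect_true(all(d$betas >= 0 & d$betas <= 1))
    expect_identical(d, generate_dataset(prof, sig, seed = s))
  }
})

test_that("informative sites correlate with age far more than noise sites", {
  ratios <- vapply(1:20, function(s) {
    d <- generate_dataset(
      dataset_profile("corr", n_samples = 200, age_min = 16, age_max = 88),
      signal_spec(), seed = s)
    r <- abs(apply(d$betas, 1L, cor, y = d$ages))
    mean(r[d$site_info$informative]) / mean(r[!d$site_info$informative])
  }, numeric(1))
  expect_true(all(ratios >= 5))
})

test_that("datasets round-trip through TSV/CSV exactly", {
  d <- tiny_dataset(seed = 4)
  betas_path <- withr::local_tempfile(fileext = ".tsv")
  samples_path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, betas_path, samples_path)
  back <- read_dataset(betas_path, samples_path)
  expect_identical(back$betas, d$betas)
  expect_identical(back$ages, d$ages)
  expect_identical(back$age_unit, d$age_unit)
})

test_that("malformed dataset files are rejected with the offending cell named", {
  d <- tiny_dataset(seed = 5)
  betas_path <- withr::local_tempfile(fileext = ".tsv")
  samples_path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, betas_path, samples_path)

  # beta out of range
  bad <- d
  bad$betas["cpg_00003", "s0002"] <- 1.2
  p1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(bad$betas, rownames = "site_id"), p1)
  expect_error(read_dataset(p1, samples_path),
               regexp = "cpg_00003.*s0002", class = "clocktol_data_error")

  # duplicated sample id in metadata
  meta <- readr::read_csv(samples_path, show_col_types = FALSE)
  meta$sample_id[2] <- meta$sample_id[1]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(meta, p2)
  expect_error(read_dataset(betas_path, p2),
               regexp = "Duplicated sample id", class = "clocktol_data_error")

  # missing age for a sample
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(meta[-1, ], p3)
  expect_error(read_dataset(betas_path, p3),
               regexp = "No age recorded", class = "clocktol_data_error")
})

test_that("non-positive ages are rejected at construction", {
  d <- tiny_dataset(seed = 6)
  ages <- d$ages
  ages[1] <- 0
  expect_error(methyl_dataset(d$betas, ages), class = "clocktol_data_error")
})
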