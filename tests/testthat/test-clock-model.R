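test_that("split sizes follow round-half-up and partitions are exact", {
  d100 <- generate_dataset(
    dataset_profile("s100", n_samples = 100, age_min = 5, age_max = 50),
    signal_spec(n_informative = 5, n_noise = 15), seed = 1)
  parts <- split_train_test(d100, 0.7, seed = 1)
  expect_equal(ncol(parts$train$betas), 70)
  expect_equal(ncol(parts$test$betas), 30)
  expect_setequal(c(names(parts$train$ages), names(parts$test$ages)),
                  names(d100$ages))
  expect_length(intersect(names(parts$train$ages), names(parts$test$ages)), 0)

  # turtle-sized cohort: 63 * 0.7 = 44.1 -> 44 train, 19 test
  d63 <- generate_dataset(dataset_profile("turtle"),
                          signal_spec(n_informative = 5, n_noise = 15), seed = 1)
  parts63 <- split_train_test(d63, 0.7, seed = 2)
  expect_equal(ncol(parts63$train$betas), 44)
  expect_equal(ncol(parts63$test$betas), 19)

  expect_identical(split_train_test(d100, 0.7, seed = 9)$train$ages,
                   split_train_test(d100, 0.7, seed = 9)$train$ages)
  expect_error(split_train_test(d100, 0), class = "clocktol_config_error")
  expect_error(split_train_test(d100, 1), class = "clocktol_config_error")
})

test_that("a noiseless linear signal is recovered almost perfectly", {
  d <- noiseless_dataset(seed = 3)
  parts <- split_train_test(d, 0.7, seed = 3)
  model <- fit_clock(parts$train, seed = 3)
  pred <- predict_ages(model, parts$test)
  expect_gte(cor(pred, parts$test$ages), 0.99)
  expect_gt(count_selected_sites(model), 0)
})

test_that("fitting is deterministic under a fixed seed", {
  d <- tiny_dataset(seed = 8)
  parts <- split_train_test(d, 0.7, seed = 8)
  m1 <- fit_clock(parts$train, seed = 11)
  m2 <- fit_clock(parts$train, seed = 11)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$lambda, m2$lambda)
})

test_that("degenerate training inputs hit their contracts", {
  d <- tiny_dataset(seed = 9)
  parts <- split_train_test(d, 0.7, seed = 9)

  # constant calibration ages cannot define a clock
  expect_error(fit_clock(parts$train, ages = rep(10, ncol(parts$train$betas))),
               class = "clocktol_data_error")

  # all-constant features: intercept-only clock predicting mean age
  flat <- parts$train
  flat$betas[] <- 0.5
  expect_warning(m <- fit_clock(flat), regexp = "intercept-only")
  expect_equal(count_selected_sites(m), 0)
  expect_equal(unname(predict_ages(m, parts$test)[1]), mean(flat$ages))

  # too few samples for the requested folds
  small <- subset_samples(parts$train, 1:5)
  expect_error(fit_clock(small, cv_folds = 10), class = "clocktol_config_error")
})

test_that("predictions equal the dot-product oracle on random sparse clocks", {
  for (s in 1:50) {
    set.seed(s)
    p <- sample(3:12, 1); n <- sample(2:8, 1)
    betas <- matrix(runif(p * n), p, n,
                    dimnames = list(sprintf("cpg_%05d", 1:p),
                                    sprintf("s%04d", 1:n)))
    ages <- runif(n, 1, 50)
    d <- methyl_dataset(betas, ages)
    k <- sample(0:p, 1)
    w <- setNames(rnorm(k, 0, 4), sample(rownames(betas), k))
    w <- w[w != 0]
    model <- manual_clock(intercept = rnorm(1, 20, 5), weights = w)
    expected <- vapply(seq_len(n), function(i) {
      model$intercept + sum(w * betas[names(w), i])
    }, numeric(1))
    pred <- suppressWarnings(predict_ages(model, d))
    expect_equal(unname(pred), expected)
  }

  # hand arithmetic: single site, weight 2, intercept 1, beta 0.5 -> 2.0
  b <- matrix(0.5, 1, 1, dimnames = list("cpg_00001", "s0001"))
  one <- methyl_dataset(b, 10)
  expect_equal(unname(predict_ages(manual_clock(1, c(cpg_00001 = 2)), one)), 2)

  # intercept-only clock predicts a constant
  expect_equal(unname(predict_ages(manual_clock(7, setNames(numeric(0), character(0))), one)), 7)

  # missing required site
  expect_error(predict_ages(manual_clock(0, c(cpg_99999 = 1)), one),
               regexp = "cpg_99999", class = "clocktol_data_error")
})

test_that("selected-site counting and overlap match set oracles", {
  m <- manual_clock(1, c(a = 0, b = 1.2, c = -0.3))
  expect_equal(count_selected_sites(m), 2)
  expect_equal(count_selected_sites(manual_clock(3, setNames(numeric(0), character(0)))), 0)

  for (s in 1:50) {
    set.seed(100 + s)
    sites <- sprintf("cpg_%05d", 1:30)
    wa <- setNames(rnorm(10), sample(sites, 10))
    wb <- setNames(rnorm(12), sample(sites, 12))
    ma <- manual_clock(0, wa); mb <- manual_clock(0, wb)
    expect_equal(selection_overlap(ma, mb),
                 length(intersect(names(wa), names(wb))))
    expect_equal(selection_overlap(ma, ma), length(wa))
  }
  expect_equal(selection_overlap(manual_clock(0, c(x = 1)),
                                 manual_clock(0, c(y = 1))), 0)
})

test_that("site selection shrinks as the penalty grows", {
  d <- tiny_dataset(seed = 12)
  parts <- split_train_test(d, 0.7, seed = 12)
  grid <- c(0.01, 0.05, 0.2, 1, 5)
  counts <- vapply(grid, function(lam) {
    count_selected_sites(fit_clock(parts$train, lambda = lam))
  }, numeric(1))
  expect_lt(counts[length(grid)], counts[1])
  expect_lte(cor(log(grid), counts, method = "spearman"), 0)
})

test_that("outlier pruning removes planted bad-age samples preferentially", {
  d <- tiny_dataset(seed = 13, n = 80, noise_sd = 0.02)
  corrupted <- names(d$ages)[1:5]
  d$ages[corrupted] <- d$ages[corrupted] * 1.8  # 80% age error planted

  res <- prune_outliers_and_refit(d, k_sd = 2.5, max_iter = 3, seed = 13)
  expect_s3_class(res$model, "clock_model")
  if (length(res$removed) > 0) {
    hit_rate <- mean(res$removed %in% corrupted)
    chance <- length(corrupted) / length(d$ages)
    expect_gt(hit_rate, chance)
  }
  # the planted outliers should be found at all
  expect_gt(length(intersect(res$removed, corrupted)), 0)

  # max_iter = 0 returns the baseline fit with nothing removed
  base <- prune_outliers_and_refit(d, k_sd = 2.5, max_iter = 0, seed = 13)
  expect_identical(base$removed, character(0))

  # a clean dataset with a huge cutoff is a fixed point
  clean <- tiny_dataset(seed = 14)
  res2 <- prune_outliers_and_refit(clean, k_sd = 50, max_iter = 3, seed = 14)
  expect_identical(res2$removed, character(0))
})

test_that("clocks serialise to JSON and back without loss", {
  d <- tiny_dataset(seed = 15)
  parts <- split_train_test(d, 0.7, seed = 15)
  model <- fit_clock(parts$train, seed = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_clock(model, path)
  back <- read_clock(path)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$weights, model$weights)
  expect_equal(back$lambda, model$lambda)
  expect_equal(back$alpha_mix, model$alpha_mix)
  expect_equal(predict_ages(back, parts$test), predict_ages(model, parts$test))
})

test_that("tidy and glance expose clock coefficients broom-style", {
  m <- manual_clock(5, c(a = 1, b = -2))
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "a", "b"))
  expect_equal(td$estimate, c(5, 1, -2))
  expect_equal(glance(m)$n_selected, 2)
})
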