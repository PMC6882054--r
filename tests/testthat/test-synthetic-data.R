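test_that("effect model validates its parameters", {
  expect_s3_class(effect_model(), "effect_model")
  expect_error(effect_model(null_prevalence = 1.2))
  expect_error(effect_model(effect_sd = 0))
  expect_error(effect_model(heterogeneity_sd = -0.1))
  expect_error(sim_config(effect_model(), n_per_arm = 1))
})

test_that("degenerate mixtures behave as point masses", {
  set.seed(1)
  all_null <- replicate(50, draw_iteration_effect(
    effect_model(null_prevalence = 1))$delta)
  expect_true(all(all_null == 0))
  no_null <- replicate(50, draw_iteration_effect(
    effect_model(null_prevalence = 0, effect_sd = 1e-12))$delta)
  expect_true(all(abs(no_null - 0.4) < 1e-9))
})

test_that("mixture proportions and non-null moments match the effect model", {
  set.seed(42)
  model <- effect_model(null_prevalence = 0.5)
  draws <- replicate(20000, draw_iteration_effect(model), simplify = FALSE)
  delta <- vapply(draws, `[[`, numeric(1), "delta")
  is_null <- vapply(draws, `[[`, logical(1), "is_null")
  expect_true(all(delta[is_null] == 0))
  # binomial check on the null fraction
  expect_lt(abs(mean(is_null) - 0.5), 3 * sqrt(0.25 / 20000))
  nn <- delta[!is_null]
  expect_lt(abs(mean(nn) - 0.4), 3 * 0.13 / sqrt(length(nn)))
  expect_lt(abs(sd(nn) - 0.13), 3 * 0.13 / sqrt(2 * (length(nn) - 1)))
})

test_that("fixed-effects generation gives identical trial effects", {
  cfg <- sim_config(effect_model(), n_per_arm = 20, n_trials = 5, seed = 3)
  set.seed(3)
  ds <- generate_dataset(cfg, iteration_delta = 0.37)
  expect_identical(ds$trial_deltas, rep(0.37, 5))
  expect_equal(dim(ds$control), c(20, 5))
  expect_equal(dim(ds$experimental), c(20, 5))
})

test_that("random-effects generation spreads trial effects by the stated sd", {
  em <- effect_model(heterogeneity_sd = 0.1)
  cfg <- sim_config(em, n_per_arm = 2, n_trials = 5000, seed = 4)
  set.seed(4)
  ds <- generate_dataset(cfg, iteration_delta = 0.4)
  devs <- ds$trial_deltas - 0.4
  expect_lt(abs(mean(devs)), 3 * 0.1 / sqrt(5000))
  expect_lt(abs(sd(devs) - 0.1), 3 * 0.1 / sqrt(2 * 4999))
})

test_that("null generation centres both arms on zero", {
  cfg <- sim_config(effect_model(), n_per_arm = 50, n_trials = 5, seed = 5)
  set.seed(5)
  diffs <- replicate(200, {
    ds <- generate_dataset(cfg, iteration_delta = 0, is_null = TRUE)
    mean(ds$experimental) - mean(ds$control)
  })
  # pooled mean difference averages 0 with sd sqrt(2/(50*5))/sqrt(200)
  expect_lt(abs(mean(diffs)), 3 * sqrt(2 / 250) / sqrt(200))
})

test_that("batches are reproducible from the seed and differ across seeds", {
  cfg <- sim_config(effect_model(), n_per_arm = 5, n_trials = 2,
                    n_replications = 4, seed = 11)
  b1 <- generate_batch(cfg)
  b2 <- generate_batch(cfg)
  expect_identical(b1, b2)
  cfg2 <- sim_config(effect_model(), n_per_arm = 5, n_trials = 2,
                     n_replications = 4, seed = 12)
  expect_false(identical(generate_batch(cfg2), b1))
})

test_that("null iteration count is binomial around the prevalence", {
  cfg <- sim_config(effect_model(null_prevalence = 0.25), n_per_arm = 2,
                    n_trials = 2, n_replications = 2000, seed = 13)
  batch <- generate_batch(cfg)
  n_null <- sum(vapply(batch, `[[`, logical(1), "is_null"))
  expect_lt(abs(n_null - 500), 3 * sqrt(2000 * 0.25 * 0.75))
})

test_that("prevalence-only changes share their non-null iterations", {
  mk <- function(prev) sim_config(effect_model(null_prevalence = prev),
                                  n_per_arm = 4, n_trials = 2,
                                  n_replications = 50, seed = 77)
  b25 <- generate_batch(mk(0.25))
  b75 <- generate_batch(mk(0.75))
  null25 <- vapply(b25, `[[`, logical(1), "is_null")
  null75 <- vapply(b75, `[[`, logical(1), "is_null")
  # nulls are nested: whatever is null at 25% prevalence is null at 75%
  expect_true(all(null75[null25]))
  shared <- !null75 # non-null under the higher prevalence
  expect_true(length(which(shared)) > 0)
  expect_identical(b25[shared], b75[shared])
})

test_that("batch export round-trips through the tabular format", {
  cfg <- sim_config(effect_model(), n_per_arm = 10, n_trials = 3,
                    n_replications = 2, seed = 21)
  batch <- generate_batch(cfg)
  tab <- batch_to_table(batch)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$mean_c[1], mean(batch[[1]]$control[, 1]))
  f <- tempfile(fileext = ".tsv")
  batch_to_table(batch, file = f)
  back <- read_trial_summaries(f)
  expect_equal(back$mean_e, tab$mean_e, tolerance = 1e-12)
  unlink(f)
})

test_that("YAML configuration files are read with defaults filled in", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("null_prevalence: 0.75", "n_per_arm: 100", "seed: 9",
               "heterogeneity_sd: 0.1"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$effect_model$null_prevalence, 0.75)
  expect_equal(cfg$effect_model$effect_mean, 0.4)
  expect_equal(cfg$effect_model$heterogeneity_sd, 0.1)
  expect_equal(cfg$n_per_arm, 100L)
  expect_equal(cfg$n_trials, 5L)
  unlink(f)
})
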