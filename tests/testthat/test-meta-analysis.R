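test_that("trial summary reproduces the standardized-mean-difference formulas", {
  s <- summarize_trial(c(0, 1, 2), c(1, 2, 3))
  expect_equal(s$effect, 1)
  expect_equal(s$variance, 6 / 9 + 1 / 12)
  # equal means kill the d^2 term
  s0 <- summarize_trial(c(1, 2, 3), c(0, 2, 4))
  expect_equal(s0$effect, 0)
  expect_equal(s0$variance, 6 / 9)
  # doubling both arms with the same summaries shrinks the variance
  big <- summarize_trial(rep(c(0, 1, 2), 2), rep(c(1, 2, 3), 2))
  expect_lt(big$variance, s$variance)
  expect_error(summarize_trial(c(1, 1), c(1, 1)), "degenerate")
})

test_that("Hedges correction shrinks d by the documented factor", {
  s <- summarize_trial(c(0, 1, 2), c(1, 2, 3), hedges_correction = TRUE)
  expect_equal(s$effect, 1 - 3 / (4 * 4 - 1))
})

test_that("fixed-effect CI matches its closed form", {
  st <- data.frame(effect = c(0.5, 0.5), variance = c(0.04, 0.04))
  r <- fixed_effect_ci(st)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$ci_lower, 0.5 - qnorm(0.975) * sqrt(0.02), tolerance = 1e-10)
  expect_equal(r$ci_lower, 0.2228, tolerance = 1e-4)
  expect_equal(r$tau_squared, 0)
  r2 <- fixed_effect_ci(data.frame(effect = c(1, 0), variance = c(1, 1)))
  expect_equal(r2$estimate, 0.5)
  expect_error(fixed_effect_ci(data.frame(effect = 1, variance = 1)),
               "at least 2")
})

test_that("DSL hand-worked example and homogeneity collapse are exact", {
  st <- data.frame(effect = c(0, 2), variance = c(1, 1))
  r <- dsl_ci(st)
  expect_equal(r$q_statistic, 2, tolerance = 1e-10)
  expect_equal(r$tau_squared, 1, tolerance = 1e-10)
  expect_equal(r$estimate, 1, tolerance = 1e-10)
  expect_equal(r$ci_upper - r$estimate, qnorm(0.975), tolerance = 1e-6)
  # identical studies collapse onto the fixed-effect result
  same <- data.frame(effect = rep(0.3, 4), variance = rep(0.1, 4))
  expect_equal(unclass(dsl_ci(same))[c("estimate", "ci_lower", "ci_upper")],
               unclass(fixed_effect_ci(same))[c("estimate", "ci_lower",
                                                "ci_upper")],
               tolerance = 1e-12)
})

test_that("HKSJ hand-worked example is exact and degenerates when homogeneous", {
  st <- data.frame(effect = c(0, 2), variance = c(1, 1))
  r <- hksj_ci(st)
  expect_equal(r$estimate, 1, tolerance = 1e-10)
  # w* = 1/2 each, q = 1, half-width t_{1,.975} * 1
  expect_equal(r$ci_upper - r$estimate, qt(0.975, 1), tolerance = 1e-6)
  expect_equal(r$ci_upper - r$estimate, 12.7062, tolerance = 1e-4)
  same <- data.frame(effect = rep(0.3, 4), variance = rep(0.1, 4))
  rs <- hksj_ci(same)
  expect_equal(rs$ci_lower, 0.3)
  expect_equal(rs$ci_upper, 0.3)
})

test_that("meta-analytic structure holds on random study sets", {
  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    st <- data.frame(effect = rnorm(k, 0.3, 0.5),
                     variance = runif(k, 0.02, 0.4))
    f <- fixed_effect_ci(st)
    d <- dsl_ci(st)
    expect_true(d$ci_lower <= d$estimate && d$estimate <= d$ci_upper)
    expect_gte(d$tau_squared, 0)
    # DSL interval is never narrower than fixed
    expect_gte((d$ci_upper - d$ci_lower) - (f$ci_upper - f$ci_lower), -1e-12)
    if (d$q_statistic <= k - 1) {
      expect_equal(d$estimate, f$estimate, tolerance = 1e-12)
    }
    # order invariance of the fixed-effect estimate
    perm <- st[sample(k), ]
    expect_equal(fixed_effect_ci(perm)$estimate, f$estimate,
                 tolerance = 1e-12)
  }
})

test_that("splitting a study into two half-weight copies leaves the pooled estimate", {
  st <- data.frame(effect = c(0.2, 0.6, 0.4), variance = c(0.1, 0.3, 0.2))
  split <- data.frame(effect = c(0.2, 0.6, 0.4, 0.4),
                      variance = c(0.1, 0.3, 0.4, 0.4))
  expect_equal(fixed_effect_ci(split)$estimate,
               fixed_effect_ci(st)$estimate, tolerance = 1e-12)
})

test_that("all three intervals agree with metafor on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(15)
  for (i in 1:10) {
    k <- sample(2:7, 1)
    y <- rnorm(k, 0.3, 0.5)
    v <- runif(k, 0.02, 0.3)
    st <- data.frame(effect = y, variance = v)
    rf <- metafor::rma(yi = y, vi = v, method = "EE")
    rd <- metafor::rma(yi = y, vi = v, method = "DL")
    rh <- metafor::rma(yi = y, vi = v, method = "DL", test = "knha")
    f <- fixed_effect_ci(st); d <- dsl_ci(st); h <- hksj_ci(st)
    expect_equal(f$estimate, as.numeric(rf$b), tolerance = 1e-10)
    expect_equal(f$ci_lower, rf$ci.lb, tolerance = 1e-10)
    expect_equal(d$tau_squared, rd$tau2, tolerance = 1e-10)
    expect_equal(d$ci_lower, rd$ci.lb, tolerance = 1e-10)
    expect_equal(h$ci_lower, rh$ci.lb, tolerance = 1e-10)
    expect_equal(h$ci_upper, rh$ci.ub, tolerance = 1e-10)
  }
})

test_that("interval containment uses the closed interval", {
  r <- fixed_effect_ci(data.frame(effect = c(0.3, 0.3),
                                  variance = c(0.01, 0.01)))
  expect_true(ci_covers(r, r$ci_lower))
  expect_true(ci_covers(r, 0.3))
  expect_false(ci_covers(r, r$ci_upper + 1e-9))
  zero <- hksj_ci(data.frame(effect = c(0.3, 0.3), variance = c(0.1, 0.1)))
  expect_true(ci_covers(zero, 0.3)) # zero-width interval at the truth
  expect_false(ci_covers(zero, 0))
})

test_that("summary-statistics input reproduces raw-data meta-analysis", {
  set.seed(16)
  cfg <- sim_config(effect_model(), n_per_arm = 15, n_trials = 4,
                    n_replications = 1, seed = 16)
  ds <- generate_batch(cfg)[[1]]
  tab <- batch_to_table(list(ds))
  f <- tempfile(fileext = ".txt")
  utils::write.table(tab, f, row.names = FALSE, quote = FALSE)
  res <- meta_analyze_summaries(read_trial_summaries(f))
  direct <- summarize_trials(ds)
  expect_equal(res$fixed$estimate, fixed_effect_ci(direct)$estimate,
               tolerance = 1e-10)
  expect_equal(res$DSL$ci_lower, dsl_ci(direct)$ci_lower, tolerance = 1e-10)
  expect_equal(res$HKSJ$ci_upper, hksj_ci(direct)$ci_upper,
               tolerance = 1e-10)
  unlink(f)
})
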