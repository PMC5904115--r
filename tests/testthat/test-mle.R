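test_that("maximum-likelihood combination formulas are exact", {
  expect_equal(mle_sigma(1, 1), 1 / sqrt(2))
  expect_equal(mle_sigma(1, 1e6), 1, tolerance = 1e-9)
  expect_equal(mle_sigma(2, 3), mle_sigma(3, 2))
  expect_error(mle_sigma(0, 1), "> 0")

  expect_equal(unname(mle_weights(1, 1)), c(0.5, 0.5))
  expect_equal(unname(mle_weights(1, 3)), c(0.25, 0.75))
  expect_equal(unname(mle_weights(0, 5)), c(0, 1))
  expect_error(mle_weights(0, 0), "reliability")
  for (i in 1:5) {
    set.seed(i)
    expect_equal(sum(mle_weights(runif(1), runif(1))), 1, tolerance = 1e-12)
  }

  expect_equal(mle_estimate(20, 50, c(0.25, 0.75)), 42.5)
  expect_equal(mle_estimate(40, 40, c(0.5, 0.5)), 40)
  expect_equal(mle_estimate(10, 70, c(0, 1)), 70)
  expect_error(mle_estimate(0, 1, c(0.6, 0.6)), "summing to 1")
})

test_that("sensitivity conversion inverts and closes the quadratic sum", {
  expect_equal(sigma_to_sensitivity(1), 1 / sqrt(2))
  expect_equal(sigma_to_sensitivity(1 / sqrt(2)), 1)
  expect_equal(sensitivity_to_sigma(sigma_to_sensitivity(5)), 5,
               tolerance = 1e-12)

  # single-cue sensitivities 0.35 (texture) and 0.16 (disparity): optimal
  # combination expressed as sensitivity equals the quadratic sum
  s_comb <- sigma_to_sensitivity(
    mle_sigma(sensitivity_to_sigma(0.16), sensitivity_to_sigma(0.35)))
  expect_equal(s_comb, sqrt(0.35^2 + 0.16^2), tolerance = 1e-12)
  expect_gte(s_comb, 0.35)
})

test_that("MLE conflict sweep never reverts", {
  ms <- mle_conflict_sweep(seq(0, 60, by = 10), sigma_delta = 6, sigma_chi = 3)
  expect_true(all(diff(abs(ms$bias_deg)) > 0))
  expect_true(all(ms$sigma_combined <= 3))
})

test_that("the normalization comparator gains from congruent cues but keeps averaging", {
  cmp0 <- normalization_comparator(slant_stimulus(0, 0, 1, 8),
                                   model_config(seed = 2))
  expect_gt(cmp0$rel_sensitivity, 1)

  cmp50 <- normalization_comparator(slant_stimulus(-25, 25, 1, 8),
                                    model_config(seed = 2))
  cmp60 <- normalization_comparator(slant_stimulus(-30, 30, 1, 8),
                                    model_config(seed = 2))
  main60 <- simulate_condition(slant_stimulus(-30, 30, 1, 8),
                               model_config(seed = 3))
  # comparator bias keeps growing with conflict; the suppressive model has
  # reverted to the reliable cue by 60 degrees of conflict
  expect_gt(cmp60$bias_deg, cmp50$bias_deg)
  expect_gt(cmp60$bias_deg, 4)
  expect_lt(abs(main60$bias_deg), 2.5)

  # disparity-only input decodes to the same slant as the main model
  cmp_d <- normalization_comparator(slant_stimulus(30, 30, 1, 0),
                                    model_config(seed = 4))
  expect_lt(abs(cmp_d$mean_estimate_deg - 30), 1)
})
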