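test_that("trial decoding is reproducible and respects mirror symmetry", {
  cfg <- model_config(n_trials = 30)
  stim <- slant_stimulus(20, 50, 1, 4)
  set.seed(5)
  a <- decode_trials(stim, cfg)
  set.seed(5)
  b <- decode_trials(stim, cfg)
  expect_identical(a, b)

  # noise-free: reflecting both cue slants about 0 reflects the estimate
  # and leaves the peak unchanged
  p <- decode_trials(slant_stimulus(20, 50, 1, 4), cfg, exact = TRUE)
  q <- decode_trials(slant_stimulus(-20, -50, 1, 4), cfg, exact = TRUE)
  expect_equal(q$slant_interp_deg, -p$slant_interp_deg, tolerance = 1e-8)
  expect_equal(q$peak_height, p$peak_height, tolerance = 1e-10)
})

test_that("single-cue sensitivity scales with the square root of intensity", {
  cfg <- model_config()
  s1 <- exact_sens(slant_stimulus(30, 30, 1, 0), cfg)
  s4 <- exact_sens(slant_stimulus(30, 30, 0, 4), cfg)
  s8 <- exact_sens(slant_stimulus(30, 30, 0, 8), cfg)
  expect_equal(s8 / s1, sqrt(8), tolerance = 1e-9)
  expect_equal(s4 / s1, 2, tolerance = 1e-9)
})

test_that("congruent equal cues approach the quadratic-sum benefit", {
  cfg <- model_config()
  ratio_exact <- exact_sens(slant_stimulus(30, 30, 1, 1), cfg) /
    exact_sens(slant_stimulus(30, 30, 1, 0), cfg)
  expect_lt(abs(ratio_exact / sqrt(2) - 1), 0.05)

  res <- simulate_condition(slant_stimulus(30, 30, 1, 1),
                            model_config(seed = 3))
  expect_lt(abs(res$bias_deg), 1.5)
  expect_lt(abs(res$rel_sensitivity / sqrt(2) - 1), 0.07)
})

test_that("equal-reliability conflicting cues yield a bimodal profile", {
  cfg <- model_config()
  tr <- decode_trials(slant_stimulus(-30, 30, 1, 1), cfg, exact = TRUE)
  expect_true(tr$bimodal)
})

test_that("an empty stimulus propagates a degenerate-estimate error", {
  expect_error(simulate_condition(slant_stimulus(0, 0, 0, 0), model_config()),
               "degenerate")
})

test_that("conflict sweeps carry the condition summaries per conflict", {
  cs <- conflict_sweep(c(0, 20), model_config(n_trials = 20, seed = 2))
  expect_s3_class(cs, "conflict_sweep")
  expect_equal(cs$conflict_deg, c(0, 20))
  expect_true(all(is.finite(cs$rel_reliability)))
})
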