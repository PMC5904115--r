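test_that("reliable-cue weight maps bias linearly and clips", {
  expect_equal(weight_from_bias(0, 50, 20), 1)
  expect_equal(weight_from_bias(30, 50, 20), 0)
  expect_equal(weight_from_bias(-15, 50, 20), 0.5)
  expect_equal(weight_from_bias(45, 50, 20), 0)
  expect_error(weight_from_bias(1, 40, 40), "undefined")
})

test_that("incongruent sensitivity is nondecreasing in the suppressive gain", {
  cfg <- model_config()
  s <- vapply(seq(0.5, 1, by = 0.125), function(b) {
    c2 <- cfg
    c2$beta <- b
    exact_sens(slant_stimulus(20, 50, 1, 4), c2)
  }, numeric(1))
  expect_true(all(diff(s) >= 0))
})

test_that("a degenerate sweep is flagged rather than crashing", {
  spec <- sweep_spec(n_sims = 5, beta_sd = 0, intensity_sd = 0, seed = 1)
  sw <- suppression_sweep(spec, model_config(n_trials = 20))
  expect_true(all(sw$correlations$degenerate))
  expect_true(all(is.na(sw$correlations$r)))
})

test_that("sweep correlation signs persist across intensity-jitter levels", {
  for (isd in c(0, 0.25)) {
    sw <- suppression_sweep(
      sweep_spec(n_sims = 60, intensity_sd = isd, seed = 8),
      model_config(n_trials = 60))
    r_inc <- sw$correlations$r[
      sw$correlations$term == "incongruent_sensitivity"]
    expect_gt(r_inc, 0.15)
  }
})

test_that("latent-cue fitting is zero at or below the quadratic sum and self-consistent above", {
  cfg <- model_config()
  expect_equal(fit_latent_cue(c(0.16, 0.16), 0.16 * sqrt(2), cfg), 0)
  expect_warning(
    L0 <- fit_latent_cue(c(0.2, 0.2), 0.25, cfg),
    "quadratic sum")
  expect_equal(L0, 0)

  target <- 0.16 * sqrt(2) * 1.15
  L <- fit_latent_cue(c(0.16, 0.16), target, cfg)
  expect_gt(L, 0)
  cond <- proscribe:::tdcs_conditions(latent_intensity = L)
  achieved <- exact_sens(cond$congruent, cfg) /
    exact_sens(cond$single_disparity, cfg)
  expect_lt(abs(achieved / (target / 0.16) - 1), 0.02)
})

test_that("the stimulation protocol enforces its stages and recovers an identity perturbation", {
  expect_error(simulate_tdcs(list(p_pos = 1), model_config()), "fit_tdcs")

  cfg <- model_config()
  L <- 0.011
  cond <- proscribe:::tdcs_conditions(latent_intensity = L)
  cal <- exact_sens(cond$single_disparity, cfg)
  obs <- c(single_disparity = 1,
           single_texture = exact_sens(cond$single_texture, cfg) / cal,
           congruent = exact_sens(cond$congruent, cfg) / cal)
  fit <- fit_tdcs(obs, L, cfg, polarity = "sham")
  expect_equal(fit$p_pos, 1, tolerance = 0.02)
  expect_equal(fit$p_neg, 1, tolerance = 0.02)
  pred <- simulate_tdcs(fit, model_config(seed = 5))
  expect_true(all(abs(pred$pct_change) < 3))
})
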