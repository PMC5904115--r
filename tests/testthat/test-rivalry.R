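test_that("rivalry parameters are validated", {
  expect_error(rivalry_params(dt = 0.2), "dt")
  expect_error(rivalry_params(tau_A = -1), "> 0")
})

test_that("without inhibition, adaptation or noise the field relaxes to its drive", {
  cfg <- model_config()
  p <- rivalry_params(gamma = 0, alpha = 0, sigma_noise = 0, T_total = 30,
                      record_every = 1, seed = 1)
  traj <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  final <- traj$X[nrow(traj$X), ]
  expect_lt(max(abs(final - traj$drive)), 1e-6)
})

test_that("trajectories are bit-identical under a fixed seed", {
  cfg <- model_config()
  p <- rivalry_params(T_total = 200, seed = 9)
  a <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  b <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  expect_identical(a$X, b$X)
})

test_that("noise-free symmetric competition stays symmetric until rounding breaks it", {
  # the symmetric state is dynamically unstable, so exact symmetry is only
  # expected over horizons short enough for rounding noise not to grow
  cfg <- model_config()
  p <- rivalry_params(sigma_noise = 0, T_total = 25, seed = 1)
  traj <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  expect_lt(max(abs(traj$X[, traj$i_delta] - traj$X[, traj$i_chi])), 1e-6)
})

test_that("mutual inhibition is required for exclusivity and adaptation for alternation", {
  cfg <- model_config()
  # no inhibition: both representations coexist, no switching
  p_g0 <- rivalry_params(gamma = 0, T_total = 1000, seed = 4)
  t_g0 <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p_g0)
  expect_equal(dominance_switches(t_g0), 0L)
  expect_true(min(tail(t_g0$X[, t_g0$i_delta], 50)) > 0 &&
                min(tail(t_g0$X[, t_g0$i_chi], 50)) > 0)

  # no adaptation: winner-take-all without alternation over a long run
  p_a0 <- rivalry_params(alpha = 0, T_total = 1500, seed = 4)
  t_a0 <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p_a0)
  expect_equal(dominance_switches(t_a0), 0L)

  # defaults: alternation between the two cue-consistent percepts
  p <- rivalry_params(T_total = 1500, seed = 3)
  tr <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  expect_gte(dominance_switches(tr), 2L)
  ep <- dominance_durations(tr)
  expect_setequal(unique(ep$percept), c("disparity", "texture"))
})

test_that("slower adaptation lengthens dominance and slows alternation", {
  cfg <- model_config()
  stats <- lapply(c(62.5, 125, 250), function(tA) {
    p <- rivalry_params(tau_A = tA, T_total = 20 * tA, seed = 7)
    tr <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
    list(dur = mean(dominance_durations(tr)$duration),
         rate = dominance_switches(tr) / p$T_total)
  })
  durs <- vapply(stats, `[[`, numeric(1), "dur")
  rates <- vapply(stats, `[[`, numeric(1), "rate")
  expect_true(all(diff(durs) > 0))
  expect_true(all(diff(rates) < 0))
})

test_that("halving the integration step leaves dominance statistics intact", {
  cfg <- model_config()
  t1 <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg,
                         rivalry_params(T_total = 1500, seed = 11))
  t2 <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg,
                         rivalry_params(T_total = 1500, seed = 11, dt = 0.025))
  d1 <- mean(dominance_durations(t1)$duration)
  d2 <- mean(dominance_durations(t2)$duration)
  expect_lt(abs(d1 - d2) / d1, 0.3)
  expect_lt(abs(dominance_switches(t1) - dominance_switches(t2)) /
              dominance_switches(t1), 0.3)
})

test_that("bistability requires conflict and comparable reliabilities", {
  cfg <- model_config()
  p <- rivalry_params(T_total = 1200, seed = 5)
  fused <- simulate_rivalry(slant_stimulus(0, 0, 1, 1), cfg, p)
  expect_equal(bistability_index(fused), 0)
  expect_equal(nrow(dominance_durations(fused)), 0L)

  unequal <- simulate_rivalry(slant_stimulus(-30, 30, 1, 8), cfg, p)
  expect_equal(bistability_index(unequal), 0)
  expect_equal(dominance_switches(unequal), 0L)

  rival <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), cfg, p)
  expect_gt(bistability_index(rival), 40)
})
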