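test_that("readout weights follow the offset cosine with tonic offset and scaling", {
  w <- build_readout(model_config())
  expect_equal(w$weights[w$offsets == 0], 1 - 0.05)
  # outermost offsets sit at a quarter cycle: cos(pi) - c
  expect_equal(w$weights[abs(w$offset_rad) == max(abs(w$offset_rad))],
               c(-1.05, -1.05))

  wb <- build_readout(model_config(beta = 0.5))
  expect_equal(min(wb$weights), -1.05 * 0.5)

  # with c = 0 the weight vanishes an eighth of a cycle out (coarse grid
  # where pi/8 is a grid offset)
  w0 <- build_readout(model_config(n_units = 9, c = 0))
  expect_equal(w0$weights[w0$offsets == 1], cos(pi / 2), tolerance = 1e-12)
})

test_that("readout agrees with a brute-force summation on toy grids", {
  for (seed in 1:3) {
    set.seed(seed)
    cfg <- tiny_cfg(beta = runif(1), c = runif(1, 0, 0.2))
    E <- matrix(runif(25), 5, 5)
    expect_equal(readout_output(E, build_readout(cfg)), brute_readout(E, cfg),
                 tolerance = 1e-12)
  }
})

test_that("readout localises a delta input and is translation invariant", {
  cfg <- model_config(c = 0)
  n <- cfg$n_units
  E <- matrix(0, n, n)
  E[19, 19] <- 5  # congruent unit at 0 degrees
  out <- readout_output(E, build_readout(cfg))
  expect_equal(which.max(out), 19)

  # a uniform grid drives every output equally (circular readout)
  U <- matrix(1, n, n)
  outU <- readout_output(U, build_readout(cfg))
  expect_equal(max(outU) - min(outU), 0, tolerance = 1e-10)
})

test_that("decoding rectifies, finds the peak, and flags pathologies", {
  cfg <- tiny_cfg()
  raw <- c(-1, 2, -1, 0.5, 0)
  est <- decode_output(raw, cfg)
  expect_true(all(est$F >= 0))
  expect_equal(est$peak_height, 2)
  expect_equal(est$slant_hat, preferred_slants(cfg)[2])

  expect_error(decode_output(rep(-0.2, 5), cfg), "degenerate")

  # two comparable peaks raise the bimodality flag
  cfg37 <- model_config()
  raw2 <- numeric(37)
  raw2[10] <- 1
  raw2[28] <- 0.9
  expect_true(decode_output(raw2, cfg37)$bimodal)
  raw2[28] <- 0.2  # secondary peak below the criterion
  expect_false(decode_output(raw2, cfg37)$bimodal)
})
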