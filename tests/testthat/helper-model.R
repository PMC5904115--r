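# small configurations and independent oracles shared across tests

tiny_cfg <- function(...) model_config(n_units = 5L, k = 2, n_trials = 20L,
                                       rate_scale = 10, ...)

# brute-force diagonal readout written directly from the definition:
# F_i = sum_j E(theta_{i-j}, theta_{i+j}) * (cos(4 j) - c), circular indices
brute_readout <- function(E, config) {
  n <- nrow(E)
  h <- pi / (n - 1)
  m <- floor(pi / 4 / h + 1e-9)
  wrap <- function(p) ((p - 1) %% (n - 1)) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in -m:m) {
      w <- cos(4 * j * h) - config$c
      w <- if (w >= 0) w * config$pos_scale else w * config$neg_scale * config$beta
      acc <- acc + E[wrap(i - j), wrap(i + j)] * w
    }
    out[i] <- acc
  }
  out
}

# four standard sweep stimuli at given intensities
std_conditions <- function(A_d = 1, A_t = 1, A_ci = 4) {
  list(single_disparity = slant_stimulus(30, 30, A_d, 0),
       single_texture = slant_stimulus(30, 30, 0, A_t),
       congruent = slant_stimulus(30, 30, A_d, A_t),
       incongruent = slant_stimulus(20, 50, A_d, A_ci))
}

exact_sens <- function(stim, cfg) {
  mean(decode_trials(stim, cfg, exact = TRUE)$sensitivity)
}
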