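#' Specification of a suppression sweep
#'
#' Parameters of the in-silico experiment that relates the model's
#' suppressive gain to its behavioural sensitivity: on each simulated
#' "observer", the negative-readout attenuation `beta` is drawn from a
#' Gaussian and the cue intensities are jittered, after which sensitivity is
#' measured for single, congruent and incongruent stimuli.
#'
#' Stimulus geometry mirrors the behavioural design: single and congruent
#' conditions at 30 degrees with unit intensities; the incongruent condition
#' pairs a disparity cue at 20 degrees (intensity 1) with a texture cue at 50
#' degrees (intensity 4, i.e. twice the sensitivity).
#'
#' @param n_sims Number of simulated observers (>= 2).
#' @param beta_mean,beta_sd Gaussian parameters for the suppressive gain;
#'   samples are clipped to `[0, 1]`.
#' @param intensity_sd SD of the Gaussian jitter applied to every cue
#'   intensity (absolute units).
#' @param A_incongruent_chi Texture intensity in the incongruent condition.
#' @param slant_single_deg Slant of the single/congruent stimuli.
#' @param slants_incongruent_deg Length-2 (disparity, texture) slants of the
#'   incongruent stimulus.
#' @param seed Integer seed (required for a reproducible sweep).
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(n_sims = 100L, beta_mean = 0.75, beta_sd = 0.1,
                       intensity_sd = 0.1, A_incongruent_chi = 4,
                       slant_single_deg = 30,
                       slants_incongruent_deg = c(20, 50), seed = 1L) {
  n_sims <- as.integer(n_sims)
  if (n_sims < 2L) stop("`n_sims` must be >= 2", call. = FALSE)
  if (beta_sd < 0 || intensity_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (length(slants_incongruent_deg) != 2L)
    stop("`slants_incongruent_deg` must have length 2", call. = FALSE)
  structure(
    list(n_sims = n_sims, beta_mean = beta_mean, beta_sd = beta_sd,
         intensity_sd = intensity_sd, A_incongruent_chi = A_incongruent_chi,
         slant_single_deg = slant_single_deg,
         slants_incongruent_deg = slants_incongruent_deg, seed = seed),
    class = "sweep_spec"
  )
}

#' Reliable-cue weight from estimation bias
#'
#' Converts the bias of a combined estimate into the weight assigned to the
#' more reliable cue: 1 when the estimate sits on the reliable cue, 0 when it
#' sits on the unreliable cue, linear in between and clipped outside.
#'
#' @param bias Signed or unsigned bias (degrees) of the estimate relative to
#'   the reliable cue.
#' @param S_reliable,S_unreliable The two cue slants (degrees; must differ).
#' @return Weight in `[0, 1]`.
#' @export
#' @examples
#' weight_from_bias(0, 50, 20)    # 1
#' weight_from_bias(30, 50, 20)   # 0
weight_from_bias <- function(bias, S_reliable, S_unreliable) {
  if (any(S_reliable == S_unreliable))
    stop("cue slants are equal: reliable-cue weight is undefined",
         call. = FALSE)
  pmin(pmax(1 - abs(bias) / abs(S_reliable - S_unreliable), 0), 1)
}

#' Suppression sweep: suppressive gain vs behavioural sensitivity
#'
#' Simulates `n_sims` observers differing in suppressive gain `beta` (and in
#' jittered cue intensities), measures model sensitivity for single-disparity,
#' single-texture, congruent and incongruent conditions, computes the
#' reliable-cue weight from the incongruent bias, and correlates everything
#' with `beta`. Stronger suppression sharpens the incongruent output profile
#' (removing the skirt of unsuppressed conflicting evidence), so incongruent
#' sensitivity rises with `beta` while single/congruent sensitivity is flat.
#'
#' @param spec A [sweep_spec()].
#' @param config A [model_config()]; its `beta` is overridden per simulation.
#' @return Object of class `suppression_sweep`: list with `simulations` (one
#'   row per observer), `correlations` (term, n, r, t, p, 95% CI), and the
#'   spec. Correlations with zero variance are flagged `degenerate` rather
#'   than an error.
#' @export
#' @examples
#' \donttest{
#' sw <- suppression_sweep(sweep_spec(n_sims = 20, seed = 1), model_config())
#' sw$correlations
#' }
suppression_sweep <- function(spec, config = model_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  set.seed(spec$seed)
  s0 <- spec$slant_single_deg
  si <- spec$slants_incongruent_deg

  rows <- purrr::map_dfr(seq_len(spec$n_sims), function(i) {
    beta <- min(max(stats::rnorm(1, spec$beta_mean, spec$beta_sd), 0), 1)
    jit <- function(A) max(stats::rnorm(1, A, spec$intensity_sd), 0)
    A_d <- jit(1)
    A_t <- jit(1)
    A_ci <- jit(spec$A_incongruent_chi)
    cfg <- config
    cfg$beta <- beta
    cfg$seed <- NULL
    sens <- function(st) {
      tr <- decode_trials(st, cfg)
      c(s = mean(tr$sensitivity, na.rm = TRUE),
        est = mean(tr$slant_interp_deg, na.rm = TRUE),
        deg = mean(tr$degenerate))
    }
    sd_ <- sens(slant_stimulus(s0, s0, A_d, 0))
    st_ <- sens(slant_stimulus(s0, s0, 0, A_t))
    co_ <- sens(slant_stimulus(s0, s0, A_d, A_t))
    ic_ <- sens(slant_stimulus(si[1], si[2], A_d, A_ci))
    tibble::tibble(
      sim = i, beta = beta, A_delta = A_d, A_texture = A_t,
      A_incongruent_chi = A_ci,
      sens_single_disparity = sd_["s"], sens_single_texture = st_["s"],
      sens_congruent = co_["s"], sens_incongruent = ic_["s"],
      est_incongruent_deg = ic_["est"],
      weight_reliable = weight_from_bias(ic_["est"] - si[2], si[2], si[1]),
      degenerate_rate = mean(c(sd_["deg"], st_["deg"], co_["deg"], ic_["deg"]))
    )
  })
  if (mean(rows$degenerate_rate) > 0.1)
    stop(sprintf(
      "degenerate decodes in %.0f%% of simulations; check intensities/config",
      100 * mean(rows$degenerate_rate)), call. = FALSE)

  single_congruent <- rowMeans(rows[, c("sens_single_disparity",
                                        "sens_single_texture",
                                        "sens_congruent")])
  cors <- dplyr::bind_rows(
    cor_row("incongruent_sensitivity", rows$beta, rows$sens_incongruent),
    cor_row("congruent_sensitivity", rows$beta, rows$sens_congruent),
    cor_row("single_disparity_sensitivity", rows$beta, rows$sens_single_disparity),
    cor_row("single_texture_sensitivity", rows$beta, rows$sens_single_texture),
    cor_row("single_congruent_sensitivity", rows$beta, single_congruent),
    cor_row("reliable_cue_weight", rows$beta, rows$weight_reliable)
  )
  structure(list(simulations = rows, correlations = cors, spec = spec,
                 config = config),
            class = "suppression_sweep")
}

# Pearson r with t-based p (n-2 df) and Fisher-z 95% CI; degenerate inputs
# (zero variance) are flagged, not errors.
cor_row <- function(term, x, y) {
  n <- sum(stats::complete.cases(x, y))
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(term = term, n = n, r = NA_real_, t = NA_real_,
                          p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                          degenerate = TRUE))
  }
  r <- stats::cor(x, y, use = "complete.obs")
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tibble::tibble(term = term, n = n, r = r, t = t, p = p,
                 ci_lo = tanh(z - 1.96 * se), ci_hi = tanh(z + 1.96 * se),
                 degenerate = FALSE)
}

#' @export
print.suppression_sweep <- function(x, ...) {
  cat(sprintf("<suppression_sweep> %d simulations, beta ~ N(%g, %g)\n",
              x$spec$n_sims, x$spec$beta_mean, x$spec$beta_sd))
  print(x$correlations)
  invisible(x)
}

# ---------------------------------------------------------------------------
# tDCS simulation: latent-cue fit, two-stage weight-scaling fit, predictions

# the four standard stimulation-experiment conditions; the latent cue is a
# frontoparallel (0 deg) residual of the other modality present in nominally
# single-cue stimuli
tdcs_conditions <- function(latent_intensity = 0, slant_deg = 40,
                            slants_incongruent_deg = c(20, 50),
                            A_incongruent_chi = 4) {
  list(
    single_disparity = slant_stimulus(slant_deg, 0, 1, latent_intensity),
    single_texture = slant_stimulus(0, slant_deg, latent_intensity, 1),
    congruent = slant_stimulus(slant_deg, slant_deg, 1, 1),
    incongruent = slant_stimulus(slants_incongruent_deg[1],
                                 slants_incongruent_deg[2],
                                 1, A_incongruent_chi)
  )
}

# noise-free model sensitivity for one stimulus under readout scaling
exact_sensitivity <- function(stimulus, config, p_pos = 1, p_neg = 1) {
  cfg <- config
  cfg$pos_scale <- p_pos
  cfg$neg_scale <- p_neg
  tr <- decode_trials(stimulus, cfg, exact = TRUE)
  tr$sensitivity
}

#' Fit the latent-cue intensity from sham behaviour
#'
#' Nominally single-cue stimuli contain residual ("latent") information from
#' the other modality signalling a frontoparallel surface, which depresses
#' measured single-cue sensitivity and lets congruent-cue sensitivity exceed
#' the quadratic sum of the measured singles. This routine finds the latent
#' intensity at which the model's congruent:single sensitivity ratios match
#' the observed ones, by bounded one-dimensional search on the noise-free
#' forward model.
#'
#' @param single_sensitivities Length-2 observed sensitivities
#'   (disparity, texture) in any common unit.
#' @param congruent_sensitivity Observed congruent-cue sensitivity, same
#'   unit.
#' @param config A [model_config()].
#' @param upper Upper bound of the search interval for the latent intensity.
#' @return Scalar latent intensity (>= 0). Zero, with a warning, when the
#'   observed congruent sensitivity does not exceed the quadratic sum.
#' @export
fit_latent_cue <- function(single_sensitivities, congruent_sensitivity,
                           config = model_config(), upper = 2) {
  stopifnot(length(single_sensitivities) == 2L)
  qsum <- sqrt(sum(single_sensitivities^2))
  if (congruent_sensitivity <= qsum) {
    if (congruent_sensitivity < qsum)
      warning("congruent sensitivity does not exceed the quadratic sum; ",
              "latent intensity set to 0", call. = FALSE)
    return(0)
  }
  target <- log(congruent_sensitivity / single_sensitivities)
  objective <- function(L) {
    cond <- tdcs_conditions(latent_intensity = L)
    s_c <- exact_sensitivity(cond$congruent, config)
    s_d <- exact_sensitivity(cond$single_disparity, config)
    s_t <- exact_sensitivity(cond$single_texture, config)
    sum((log(s_c / c(s_d, s_t)) - target)^2)
  }
  # the objective is not unimodal over a wide range (a strong latent cue
  # reshapes the single-cue profile non-monotonically), so bracket on a
  # coarse grid before the local search
  grid <- seq(0, upper, length.out = 81)
  vals <- vapply(grid, objective, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  fit <- stats::optimize(objective, c(lo, hi))
  if (fit$objective > min(vals) + 1e-9)
    return(grid[i])
  if (fit$objective > objective(0) + 1e-9 && i == length(grid))
    stop("latent-cue fit failed to bracket a minimum; residual = ",
         signif(fit$objective, 3), call. = FALSE)
  fit$minimum
}

#' Fit stimulation scaling factors on single- and congruent-cue data
#'
#' Stage one of the stimulation protocol: finds the multiplicative factors
#' `(p_pos, p_neg)` on the positive and negative readout weights (both in
#' `[0, 1]`, the sham condition being `(1, 1)`) that best reproduce observed
#' single- and congruent-cue sensitivities under a given polarity, by a
#' 41 x 41 grid search refined with bounded quasi-Newton steps on the
#' noise-free forward model. Incongruent data are deliberately excluded: they
#' are reserved for the stage-two generalisation test.
#'
#' @param observed Named numeric with elements `single_disparity`,
#'   `single_texture`, `congruent`: sensitivities in sham-calibrated units
#'   (sham single-disparity = 1).
#' @param latent_intensity Latent-cue intensity from [fit_latent_cue()],
#'   held fixed.
#' @param config A [model_config()].
#' @param polarity Label stored with the fit ("anodal", "cathodal", "sham").
#' @return Object of class `tdcs_fit`: `p_pos`, `p_neg`, `polarity`,
#'   `latent_intensity`, fitted/observed values and residual sum of squares.
#' @export
fit_tdcs <- function(observed, latent_intensity, config = model_config(),
                     polarity = "cathodal") {
  need <- c("single_disparity", "single_texture", "congruent")
  if (!all(need %in% names(observed)))
    stop("`observed` must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  cond <- tdcs_conditions(latent_intensity = latent_intensity)
  # calibration: sham single-disparity defines the unit
  cal <- exact_sensitivity(cond$single_disparity, config)
  predict3 <- function(p) {
    c(single_disparity = exact_sensitivity(cond$single_disparity, config, p[1], p[2]),
      single_texture = exact_sensitivity(cond$single_texture, config, p[1], p[2]),
      congruent = exact_sensitivity(cond$congruent, config, p[1], p[2])) / cal
  }
  obj <- function(p) sum((predict3(p) - observed[need])^2)
  grid <- seq(0, 1, length.out = 41)
  vals <- outer(grid, grid, Vectorize(function(a, b) obj(c(a, b))))
  best <- arrayInd(which.min(vals), dim(vals))
  start <- c(grid[best[1]], grid[best[2]])
  ref <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, 1))
  structure(
    list(p_pos = ref$par[1], p_neg = ref$par[2], polarity = polarity,
         latent_intensity = latent_intensity,
         fitted = predict3(ref$par), observed = observed[need],
         rss = ref$value, calibration = cal),
    class = "tdcs_fit"
  )
}

#' @export
print.tdcs_fit <- function(x, ...) {
  cat(sprintf("<tdcs_fit> %s: p_pos = %.3f, p_neg = %.3f (rss %.2e)\n",
              x$polarity, x$p_pos, x$p_neg, x$rss))
  invisible(x)
}

#' Predict stimulation effects with frozen parameters
#'
#' Stage two of the stimulation protocol: with `(p_pos, p_neg)` frozen from
#' [fit_tdcs()], simulates Poisson-trial sensitivity for all four conditions
#' and reports each as a percentage change against the sham prediction
#' (`p_pos = p_neg = 1`, same latent cue). The interesting output is the
#' incongruent row, which played no part in the fit.
#'
#' @param fit A `tdcs_fit` object (stage one must run first).
#' @param config A [model_config()]; `config$seed` seeds the Poisson draws.
#' @return Tibble of class `tdcs_prediction`: condition, sham and stimulated
#'   sensitivity (sham-calibrated units), `pct_change`.
#' @export
simulate_tdcs <- function(fit, config = model_config()) {
  if (!inherits(fit, "tdcs_fit"))
    stop("stage-two prediction requires a `tdcs_fit`; run `fit_tdcs()` first",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  cond <- tdcs_conditions(latent_intensity = fit$latent_intensity)
  mc_sens <- function(st, p_pos, p_neg) {
    cfg <- config
    cfg$pos_scale <- p_pos
    cfg$neg_scale <- p_neg
    cfg$seed <- NULL
    mean(decode_trials(st, cfg)$sensitivity, na.rm = TRUE)
  }
  out <- purrr::map_dfr(names(cond), function(nm) {
    sham <- mc_sens(cond[[nm]], 1, 1) / fit$calibration
    stim <- mc_sens(cond[[nm]], fit$p_pos, fit$p_neg) / fit$calibration
    tibble::tibble(condition = nm, polarity = fit$polarity,
                   sham_sensitivity = sham, stim_sensitivity = stim,
                   pct_change = 100 * (stim - sham) / sham)
  })
  class(out) <- c("tdcs_prediction", class(out))
  out
}
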