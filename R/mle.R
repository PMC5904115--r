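#' Maximum-likelihood cue combination
#'
#' Closed-form predictions of the standard (non-robust) Gaussian fusion
#' model: the combined estimate is the reliability-weighted average of the
#' single-cue estimates and the combined SD is always below either single-cue
#' SD, whatever the size of the cue conflict.
#'
#' @param sigma_delta,sigma_chi Single-cue estimate SDs (degrees, > 0).
#' @return `mle_sigma()`: the combined SD,
#'   `sqrt(sigma_delta^2 * sigma_chi^2 / (sigma_delta^2 + sigma_chi^2))`.
#' @export
#' @examples
#' mle_sigma(1, 1)                # 1/sqrt(2)
#' mle_weights(1, 3)              # c(0.25, 0.75)
#' mle_estimate(20, 50, c(0.25, 0.75))  # 42.5
mle_sigma <- function(sigma_delta, sigma_chi) {
  if (any(c(sigma_delta, sigma_chi) <= 0))
    stop("SDs must be > 0", call. = FALSE)
  sqrt(sigma_delta^2 * sigma_chi^2 / (sigma_delta^2 + sigma_chi^2))
}

#' @rdname mle_sigma
#' @param r_delta,r_chi Cue reliabilities (inverse variances, >= 0, not both
#'   zero).
#' @return `mle_weights()`: named numeric `c(w_delta, w_chi)` summing to 1.
#' @export
mle_weights <- function(r_delta, r_chi) {
  if (r_delta < 0 || r_chi < 0)
    stop("reliabilities must be >= 0", call. = FALSE)
  if (r_delta + r_chi == 0)
    stop("at least one reliability must be > 0", call. = FALSE)
  c(w_delta = r_delta / (r_delta + r_chi),
    w_chi = r_chi / (r_delta + r_chi))
}

#' @rdname mle_sigma
#' @param S_delta,S_chi Cue slants (degrees).
#' @param weights Length-2 weights summing to 1 (e.g. from [mle_weights()]).
#' @return `mle_estimate()`: the combined slant `w_delta*S_delta +
#'   w_chi*S_chi` (degrees).
#' @export
mle_estimate <- function(S_delta, S_chi, weights) {
  if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-9)
    stop("`weights` must be two values summing to 1", call. = FALSE)
  unname(weights[1] * S_delta + weights[2] * S_chi)
}

#' Convert estimate SD to discrimination sensitivity
#'
#' In a two-interval forced-choice task both intervals carry estimation
#' noise, so the discrimination threshold is `sigma * sqrt(2)` and
#' sensitivity (the reciprocal of the just-noticeable difference) is
#' `s = 1 / (sigma * sqrt(2))`.
#'
#' @param sigma Estimate SD (degrees, > 0).
#' @return Sensitivity in 1/degrees.
#' @export
#' @examples
#' sigma_to_sensitivity(1)            # 1/sqrt(2)
#' sensitivity_to_sigma(sigma_to_sensitivity(5))  # 5
sigma_to_sensitivity <- function(sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  1 / (sigma * sqrt(2))
}

#' @rdname sigma_to_sensitivity
#' @param s Sensitivity (1/degrees, > 0).
#' @export
sensitivity_to_sigma <- function(s) {
  if (any(s <= 0)) stop("`s` must be > 0", call. = FALSE)
  1 / (s * sqrt(2))
}

#' MLE prediction table for a conflict sweep
#'
#' Convenience wrapper returning, for each conflict, the optimal-fusion bias
#' (relative to the more reliable cue) and combined sensitivity implied by
#' the single-cue SDs. Useful as the non-robust baseline against the
#' population model's conflict sweep: the MLE bias grows linearly with
#' conflict and never reverts.
#'
#' @param conflicts_deg Conflict magnitudes (degrees).
#' @param sigma_delta,sigma_chi Single-cue SDs (degrees).
#' @param center_deg Midpoint of the two cue slants.
#' @return Tibble with `conflict_deg`, `estimate_deg`, `bias_deg`,
#'   `sigma_combined`, `sensitivity_combined`, `model` = "mle".
#' @export
mle_conflict_sweep <- function(conflicts_deg, sigma_delta, sigma_chi,
                               center_deg = 0) {
  w <- mle_weights(1 / sigma_delta^2, 1 / sigma_chi^2)
  rel_chi <- sigma_chi <= sigma_delta
  purrr::map_dfr(conflicts_deg, function(d) {
    S_d <- center_deg - d / 2
    S_c <- center_deg + d / 2
    est <- mle_estimate(S_d, S_c, w)
    s_rel <- if (rel_chi) S_c else S_d
    toward <- if (d == 0) 1 else if (rel_chi) -1 else 1
    tibble::tibble(
      conflict_deg = d,
      estimate_deg = est,
      bias_deg = (est - s_rel) * toward,
      sigma_combined = mle_sigma(sigma_delta, sigma_chi),
      sensitivity_combined = sigma_to_sensitivity(mle_sigma(sigma_delta, sigma_chi)),
      model = "mle"
    )
  })
}

#' Simplified divisive-normalization comparator
#'
#' An illustrative stand-in for a normalization-style combination model, not
#' a faithful re-implementation of any published variant: only congruent
#' combination units are formed (`f_delta(i) + f_chi(i)` on the diagonal),
#' their activity is divided by the summed population activity, and the slant
#' estimate is read out as the population vector (activity-weighted mean).
#' It shows the combination benefit for congruent cues but keeps averaging
#' under large conflict — it never reverts to the reliable cue, which is the
#' qualitative failure the suppressive readout corrects.
#'
#' @param stimulus A [slant_stimulus()].
#' @param config A [model_config()]; `n_trials`, `k` and `rate_scale` are
#'   honoured, the readout parameters are not used.
#' @param exact Use noise-free rates.
#' @param sigma_semi Semi-saturation constant added to the normalization
#'   denominator (spikes; default 1).
#' @return One-row tibble like [simulate_condition()]'s, with
#'   `model = "normalization"` (single-cue reference columns included).
#' @export
normalization_comparator <- function(stimulus, config, exact = FALSE,
                                     sigma_semi = 1) {
  prefs <- preferred_slants(config)
  decode_norm <- function(stim) {
    fd <- unimodal_rates(stim$slant_delta, stim$A_delta, config, prefs)
    fc <- unimodal_rates(stim$slant_chi, stim$A_chi, config, prefs)
    if (exact) {
      Rd <- matrix(fd, nrow = 1)
      Rc <- matrix(fc, nrow = 1)
    } else {
      Rd <- sample_poisson(fd, config$n_trials)
      Rc <- sample_poisson(fc, config$n_trials)
    }
    E <- Rd + Rc                       # congruent units only
    E <- E / (sigma_semi + rowSums(E)) # divisive normalization
    n <- config$n_units
    G <- E[, -n, drop = FALSE]
    pd <- rad2deg(prefs[-n])
    peak <- apply(G, 1, max)
    ok <- peak > 0
    tot <- rowSums(G)
    mu <- as.vector(G %*% pd) / ifelse(tot > 0, tot, NA_real_)
    # sensitivity = precision of the population-vector estimate across
    # trials (division by total activity normalises shape away, so the
    # combination benefit lives in the trial-to-trial variance)
    est_sd <- stats::sd(mu[ok])
    list(est = mean(mu[ok]),
         peak = mean(peak[ok]),
         sens = if (is.na(est_sd) || est_sd == 0) NA_real_ else 1 / est_sd)
  }
  comb <- decode_norm(stimulus)
  single_d <- stimulus
  single_d$A_chi <- 0
  single_t <- stimulus
  single_t$A_delta <- 0
  dd <- if (stimulus$A_delta > 0) decode_norm(single_d) else list(est = NA, peak = NA, sens = NA)
  tt <- if (stimulus$A_chi > 0) decode_norm(single_t) else list(est = NA, peak = NA, sens = NA)
  tex_rel <- !is.na(tt$peak) && (is.na(dd$peak) || tt$peak >= dd$peak)
  s_rel <- if (tex_rel) rad2deg(stimulus$slant_chi) else rad2deg(stimulus$slant_delta)
  s_unrel <- if (tex_rel) rad2deg(stimulus$slant_delta) else rad2deg(stimulus$slant_chi)
  toward <- if (s_unrel == s_rel) 1 else sign(s_unrel - s_rel)
  tibble::tibble(
    model = "normalization",
    slant_delta_deg = rad2deg(stimulus$slant_delta),
    slant_chi_deg = rad2deg(stimulus$slant_chi),
    A_delta = stimulus$A_delta, A_chi = stimulus$A_chi,
    mean_estimate_deg = comb$est,
    bias_deg = (comb$est - s_rel) * toward,
    mean_peak = comb$peak,
    sensitivity = comb$sens,
    sensitivity_single_disparity = dd$sens,
    sensitivity_single_texture = tt$sens,
    rel_sensitivity = comb$sens / dd$sens
  )
}
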