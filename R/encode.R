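#' Unimodal population response to a slant cue
#'
#' Mean firing rate of the bank of slant-tuned units for one cue. Each unit's
#' receptive field is a von Mises function of slant,
#' `f(theta) = A * rate_scale * exp(k * cos(2 * (theta - theta_pref))) / exp(k)`,
#' so the peak rate equals `A * rate_scale` at the preferred slant. The
#' factor 2 maps the slant range `[-90, 90]` degrees onto one full cycle;
#' rates scale exactly linearly with intensity.
#'
#' @param slant_deg Stimulus slant in degrees, in `[-90, 90]`.
#' @param intensity Cue intensity (>= 0); 0 yields an all-zero response.
#' @param config A [model_config()].
#' @param cue_label Optional label ("disparity"/"texture") carried in the
#'   result.
#'
#' @return A tibble of class `unimodal_response` with columns `pref`
#'   (preferred slant, radians), `pref_deg`, `rate` (mean spikes/interval),
#'   and `cue`.
#' @export
#' @examples
#' r <- unimodal_response(30, 1, model_config())
#' r$pref_deg[which.max(r$rate)]
unimodal_response <- function(slant_deg, intensity, config, cue_label = NA_character_) {
  if (!is.finite(slant_deg) || abs(slant_deg) > 90)
    stop("`slant_deg` must lie in [-90, 90]", call. = FALSE)
  if (!is.finite(intensity) || intensity < 0)
    stop("`intensity` must be >= 0", call. = FALSE)
  prefs <- preferred_slants(config)
  rate <- intensity * config$rate_scale *
    exp(config$k * (cos(2 * (deg2rad(slant_deg) - prefs)) - 1))
  out <- tibble::tibble(pref = prefs, pref_deg = rad2deg(prefs),
                        rate = rate, cue = cue_label)
  class(out) <- c("unimodal_response", class(out))
  out
}

# rate vector only; used on the hot path
unimodal_rates <- function(slant_rad, intensity, config, prefs) {
  intensity * config$rate_scale *
    exp(config$k * (cos(2 * (slant_rad - prefs)) - 1))
}

#' Poisson spike counts for a rate vector
#'
#' Draws independent Poisson counts for each unit on each trial, the noise
#' model used throughout the simulations.
#'
#' @param rates Nonnegative mean rates (spikes/interval), one per unit.
#' @param n_trials Number of repetitions.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Integer matrix, `n_trials` rows by `length(rates)` columns.
#' @export
#' @examples
#' counts <- sample_poisson(c(0, 5, 10), 4, seed = 1)
#' dim(counts)
sample_poisson <- function(rates, n_trials, seed = NULL) {
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("`rates` must be finite and >= 0", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rpois(n_trials * length(rates), rep(rates, each = n_trials)),
         nrow = n_trials)
}

#' Combination-unit activity
#'
#' Every pairing of a disparity-tuned and a texture-tuned unit drives one
#' combination unit, which sums its two inputs sublinearly:
#' `E(i, j) = sqrt(f_delta(i) + f_chi(j))`. Diagonal cells are "congruent"
#' units; off-diagonal cells are "incongruent" units tuned to cue conflict.
#' Doubling both inputs scales every cell by exactly `sqrt(2)`.
#'
#' @param f_delta,f_chi Nonnegative response vectors of equal length
#'   (disparity and texture unimodal rates).
#'
#' @return Matrix `E` with disparity preference on rows and texture
#'   preference on columns.
#' @export
#' @examples
#' combine_cues(c(0, 4), c(5, 0))[1, 1]  # sqrt(0 + 5)
combine_cues <- function(f_delta, f_chi) {
  if (length(f_delta) != length(f_chi))
    stop("input vectors must have equal length", call. = FALSE)
  if (any(f_delta < 0) || any(f_chi < 0))
    stop("unimodal responses must be >= 0", call. = FALSE)
  sqrt(outer(f_delta, f_chi, `+`))
}
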