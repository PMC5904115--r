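#' Model configuration
#'
#' Builds the configuration object shared by every simulation routine: the
#' size and tuning of the unimodal encoding layers, the tonic-inhibition
#' offset of the cosine readout, the suppressive gain on negative readout
#' weights, and the Poisson sampling settings.
#'
#' Preferred slants are `n_units` evenly spaced values spanning -90 to +90
#' degrees, so `n_units` must be odd (0 degrees is then always a preference).
#' All angles are degrees at the user-facing boundary and radians internally.
#'
#' @param n_units Number of unimodal preferences per cue (odd, >= 3).
#' @param k Von Mises tuning concentration (unitless, > 0). The default 40
#'   gives a slant-tuning bandwidth (full width at half maximum) of about
#'   10.7 degrees.
#' @param c Tonic-inhibition ("temperature") offset subtracted from the
#'   cosine readout weights.
#' @param beta Attenuation of the negative readout weights, in `[0, 1]`.
#'   `beta = 1` is full suppression; smaller values weaken it.
#' @param pos_scale,neg_scale Multiplicative factors on the positive and
#'   negative readout weights, in `[0, 1]`; used to emulate excitatory /
#'   inhibitory perturbation (e.g. direct-current stimulation).
#' @param n_trials Poisson repetitions per condition.
#' @param rate_scale Mean spikes per interval per unit cue intensity at the
#'   tuning peak (calibration constant).
#' @param bimodal_frac Secondary local maxima at least this fraction of the
#'   global peak raise the bimodality flag.
#' @param seed Optional integer seed applied by the top-level simulation
#'   entry points.
#'
#' @return An object of class `model_config` (a named list).
#' @export
#' @examples
#' cfg <- model_config()
#' cfg$n_units
model_config <- function(n_units = 37L, k = 40, c = 0.05, beta = 1,
                         pos_scale = 1, neg_scale = 1,
                         n_trials = 100L, rate_scale = 100,
                         bimodal_frac = 0.7, seed = NULL) {
  n_units <- as.integer(n_units)
  if (n_units < 3L || n_units %% 2L == 0L)
    stop("`n_units` must be an odd integer >= 3", call. = FALSE)
  if (k <= 0) stop("`k` must be > 0", call. = FALSE)
  for (nm in c("beta", "pos_scale", "neg_scale")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("`n_trials` must be >= 1", call. = FALSE)
  if (rate_scale <= 0) stop("`rate_scale` must be > 0", call. = FALSE)
  structure(
    list(n_units = n_units, k = k, c = c, beta = beta,
         pos_scale = pos_scale, neg_scale = neg_scale,
         n_trials = n_trials, rate_scale = rate_scale,
         bimodal_frac = bimodal_frac, seed = seed),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  %d units/cue (%.1f deg spacing), k = %g, c = %g\n",
              x$n_units, 180 / (x$n_units - 1), x$k, x$c))
  cat(sprintf("  beta = %g, pos_scale = %g, neg_scale = %g\n",
              x$beta, x$pos_scale, x$neg_scale))
  cat(sprintf("  n_trials = %d, rate_scale = %g\n", x$n_trials, x$rate_scale))
  invisible(x)
}

#' Slant stimulus
#'
#' A stimulus is the pair of slants signalled by the disparity and texture
#' cues together with their intensities. Intensity 0 means the cue is absent.
#'
#' @param slant_delta_deg,slant_chi_deg Disparity- and texture-defined slant,
#'   degrees in `[-90, 90]`.
#' @param A_delta,A_chi Cue intensities (unitless, >= 0).
#'
#' @return An object of class `slant_stimulus`.
#' @export
#' @examples
#' slant_stimulus(20, 50, A_delta = 1, A_chi = 4)
slant_stimulus <- function(slant_delta_deg = 0, slant_chi_deg = 0,
                           A_delta = 1, A_chi = 1) {
  for (s in c(slant_delta_deg, slant_chi_deg)) {
    if (!is.finite(s) || abs(s) > 90)
      stop("cue slants must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (A_delta < 0 || A_chi < 0)
    stop("cue intensities must be >= 0", call. = FALSE)
  structure(
    list(slant_delta = deg2rad(slant_delta_deg),
         slant_chi = deg2rad(slant_chi_deg),
         A_delta = A_delta, A_chi = A_chi),
    class = "slant_stimulus"
  )
}

#' @export
print.slant_stimulus <- function(x, ...) {
  cat(sprintf("<slant_stimulus> disparity %.1f deg (A = %g), texture %.1f deg (A = %g)\n",
              rad2deg(x$slant_delta), x$A_delta, rad2deg(x$slant_chi), x$A_chi))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Preferred slants of the unimodal layers
#'
#' @param config A [model_config()].
#' @return Numeric vector of preferred slants in radians, evenly spaced over
#'   `[-pi/2, pi/2]`.
#' @export
preferred_slants <- function(config) {
  seq(-pi / 2, pi / 2, length.out = config$n_units)
}
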