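#' Cosine readout weights
#'
#' Output units pool combination units lying on the anti-diagonal through
#' their own preference: the unit at preference `i` receives
#' `E(i - j, i + j)` for offsets `j` up to a quarter cycle, weighted by
#' `cos(4 j) - c`. The offset `c` is a tonic-inhibition ("temperature") term
#' that makes distant-conflict combination units suppressive. The positive
#' part of the weights is scaled by `pos_scale` and the negative part by
#' `neg_scale * beta`, which is how suppressive-gain and stimulation
#' perturbations enter the model.
#'
#' @param config A [model_config()].
#'
#' @return An object of class `readout_weights`: a list with integer
#'   `offsets` (grid steps), `offset_rad`, and the scaled `weights`.
#' @export
#' @examples
#' w <- build_readout(model_config())
#' w$weights[w$offsets == 0]  # cos(0) - 0.05
build_readout <- function(config) {
  h <- pi / (config$n_units - 1)
  m <- floor(pi / 4 / h + 1e-9)
  offsets <- seq.int(-m, m)
  j <- offsets * h
  w <- cos(4 * j) - config$c
  w <- ifelse(w >= 0, w * config$pos_scale, w * config$neg_scale * config$beta)
  structure(list(offsets = offsets, offset_rad = j, weights = w),
            class = "readout_weights")
}

#' Diagonal readout of the combination grid
#'
#' Computes the raw output profile `F_i = sum_j w(j) * E(i - j, i + j)`.
#' Because the von Mises tuning (with its factor-2 angle mapping) makes every
#' profile periodic over the 180-degree slant range, offsets are wrapped
#' circularly: the preference grid's two endpoints (-90 and +90 degrees)
#' alias to the same physical unit. This keeps the readout exactly
#' translation invariant and free of rim artefacts.
#'
#' @param E Combination-unit matrix from [combine_cues()].
#' @param weights A `readout_weights` object from [build_readout()].
#'
#' @return Numeric vector of raw (signed) output activities, one per
#'   preference.
#' @export
readout_output <- function(E, weights) {
  n <- nrow(E)
  if (ncol(E) != n)
    stop("`E` must be a square combination grid", call. = FALSE)
  if (max(abs(weights$offsets)) >= n)
    stop("readout offsets exceed grid size; mismatched config", call. = FALSE)
  out <- numeric(n)
  i <- seq_len(n)
  for (idx in seq_along(weights$offsets)) {
    j <- weights$offsets[idx]
    out <- out + weights$weights[idx] * E[cbind(wrap_index(i - j, n),
                                                wrap_index(i + j, n))]
  }
  out
}

# circular index over the period of the preference grid: the duplicated
# endpoint (index n, +90 deg) aliases to index 1 (-90 deg)
wrap_index <- function(i, n) ((i - 1L) %% (n - 1L)) + 1L

#' Decode a raw output profile
#'
#' Converts raw output activity to a firing-rate profile by thresholding
#' negative values at zero, then reads the estimate off the peak: the peak
#' position is the slant estimate and the peak height the reliability proxy.
#' Profiles with a secondary local maximum at least `bimodal_frac` of the
#' global peak are flagged bimodal; peaks in the outer two grid points are
#' flagged as edge-limited.
#'
#' @param raw Raw output vector from [readout_output()].
#' @param config A [model_config()].
#'
#' @return An object of class `slant_estimate`: list with `F` (rectified
#'   profile), `slant_hat` (radians), `slant_hat_deg`, `peak_height`,
#'   `bimodal`, and `edge` flags.
#' @export
decode_output <- function(raw, config) {
  if (length(raw) != config$n_units)
    stop("`raw` must have length `n_units`", call. = FALSE)
  f <- pmax(raw, 0)
  if (all(f == 0))
    stop("degenerate estimate: rectified output is identically zero",
         call. = FALSE)
  prefs <- preferred_slants(config)
  i <- which.max(f)
  peaks <- local_maxima(f)
  bimodal <- sum(f[peaks] >= config$bimodal_frac * f[i]) >= 2L
  structure(
    list(F = f, slant_hat = prefs[i], slant_hat_deg = rad2deg(prefs[i]),
         peak_height = f[i], bimodal = bimodal,
         edge = i <= 2L || i >= config$n_units - 1L),
    class = "slant_estimate"
  )
}

#' @export
print.slant_estimate <- function(x, ...) {
  cat(sprintf("<slant_estimate> %.1f deg (peak %.2f)%s%s\n",
              x$slant_hat_deg, x$peak_height,
              if (x$bimodal) ", bimodal" else "",
              if (x$edge) ", edge-limited" else ""))
  invisible(x)
}

# circular local maxima over the non-duplicated part of the grid
local_maxima <- function(f) {
  n <- length(f)
  g <- f[-n]  # drop the aliased endpoint
  m <- length(g)
  left <- g[c(m, seq_len(m - 1))]
  right <- g[c(seq_len(m - 1) + 1, 1)]
  which(g > 0 & g >= left & g > right)
}
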