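#' Parameters of the rivalry dynamics
#'
#' The output layer is extended with mutual inhibition, slow adaptation and
#' additive noise so that an ambiguous (bimodal) drive produces spontaneous
#' alternation between the two cue-consistent interpretations:
#' `tau dX/dt = F - (1 + A) X + W(0, sigma) - gamma * L S[X]` and
#' `tau_A dA/dt = -A + alpha S[X]`, where `S` is a Naka-Rushton sigmoid and
#' `L` the half-wave-rectified lateral kernel `[-cos(2 (theta_j - theta_i))]_+`
#' (maximal inhibition between maximally different slants, none between
#' neighbours).
#'
#' @param tau Activity time constant (arbitrary time unit).
#' @param tau_A Adaptation time constant (same unit; slow).
#' @param gamma Mutual-inhibition strength.
#' @param alpha Adaptation strength.
#' @param sigma_noise SD of the additive Gaussian noise.
#' @param dt Euler-Maruyama step; must satisfy `dt < tau/10`.
#' @param T_total Total simulated duration.
#' @param naka_n Naka-Rushton exponent.
#' @param naka_c50 Half-saturation constant, in units of the (normalised)
#'   single-cue drive peak; `NULL` = 0.5.
#' @param record_every Store every this-many-th step in the trajectory.
#' @param seed Integer seed.
#' @return Object of class `rivalry_params`.
#' @export
rivalry_params <- function(tau = 1, tau_A = 125, gamma = 7, alpha = 7,
                           sigma_noise = 0.005, dt = 0.05 * tau,
                           T_total = 50 * tau_A, naka_n = 2, naka_c50 = 0.5,
                           record_every = 10L, seed = 1L) {
  if (tau <= 0 || tau_A <= 0) stop("time constants must be > 0", call. = FALSE)
  if (dt >= tau / 10) stop("`dt` must be < tau/10", call. = FALSE)
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  structure(
    list(tau = tau, tau_A = tau_A, gamma = gamma, alpha = alpha,
         sigma_noise = sigma_noise, dt = dt, T_total = T_total,
         naka_n = naka_n, naka_c50 = naka_c50,
         record_every = as.integer(record_every), seed = seed),
    class = "rivalry_params"
  )
}

naka_rushton <- function(x, n, c50) {
  x <- pmax(x, 0)
  x^n / (x^n + c50^n)
}

# Half-wave-rectified lateral inhibition kernel over preferences (radians),
# scaled by the grid spacing so the inhibition integral - and hence the
# dynamical regime at a given gamma - does not depend on n_units.
lateral_kernel <- function(prefs) {
  D <- outer(prefs, prefs, `-`)
  pmax(-cos(2 * D), 0) * (pi / length(prefs))
}

#' One Euler-Maruyama step of the rivalry dynamics
#'
#' Exposed mainly for testing; [simulate_rivalry()] drives the loop.
#'
#' @param state List with numeric vectors `X` (activity) and `A`
#'   (adaptation).
#' @param drive Constant input vector `F` (the rectified, normalised output
#'   profile of the stimulus).
#' @param L Lateral kernel matrix from the same preference grid.
#' @param params A [rivalry_params()].
#' @param noise Pre-drawn standard-normal vector (length of `X`), or `NULL`
#'   to draw internally.
#' @return Updated state list.
#' @export
rivalry_step <- function(state, drive, L, params, noise = NULL) {
  if (any(!is.finite(state$X)) || any(!is.finite(state$A)))
    stop("non-finite state entering rivalry_step; reduce dt or noise",
         call. = FALSE)
  S <- naka_rushton(state$X, params$naka_n, params$naka_c50)
  if (is.null(noise)) noise <- stats::rnorm(length(state$X))
  dX <- (drive - (1 + state$A) * state$X - params$gamma * as.vector(L %*% S)) *
    params$dt / params$tau +
    params$sigma_noise * sqrt(params$dt) / params$tau * noise
  dA <- (-state$A + params$alpha * S) * params$dt / params$tau_A
  list(X = state$X + dX, A = state$A + dA)
}

#' Simulate perceptual rivalry driven by a cue-conflict stimulus
#'
#' The stimulus is passed through the population model noise-free; the
#' rectified output profile (normalised so that a unit-intensity single cue
#' would peak at 1) is the constant drive `F`. With two conflicting cues of
#' equal reliability the drive is bimodal and the output layer alternates
#' between the two cue-consistent interpretations; with strongly unequal
#' reliabilities one interpretation stays dominant throughout.
#'
#' @param stimulus A [slant_stimulus()].
#' @param config A [model_config()].
#' @param params A [rivalry_params()].
#' @return Object of class `rivalry_trajectory`: list with tibble `trace`
#'   (`t`, `unit` (degrees), `X`, `A` in long format), `drive`, the two
#'   cue-consistent unit indices, `dominance` (tibble `t`, `label`), and the
#'   inputs.
#' @export
#' @examples
#' \donttest{
#' traj <- simulate_rivalry(slant_stimulus(-30, 30, 1, 1), model_config(),
#'                          rivalry_params(T_total = 500, seed = 2))
#' }
simulate_rivalry <- function(stimulus, config, params) {
  set.seed(params$seed)
  prefs <- preferred_slants(config)[-config$n_units]
  drv_full <- decode_trials(stimulus, config, exact = TRUE)
  # rebuild the rectified profile and normalise by the single-cue peak
  F_raw <- noise_free_profile(stimulus, config)
  ref <- slant_stimulus(rad2deg(stimulus$slant_delta), 0, 1, 0)
  F_ref <- max(noise_free_profile(ref, config))
  drive <- pmax(F_raw, 0)[-config$n_units] / F_ref

  L <- lateral_kernel(prefs)
  n_steps <- ceiling(params$T_total / params$dt)
  keep <- seq(1L, n_steps, by = params$record_every)
  n_keep <- length(keep)
  Xs <- matrix(NA_real_, n_keep, length(prefs))
  As <- matrix(NA_real_, n_keep, length(prefs))
  state <- list(X = rep(0, length(prefs)), A = rep(0, length(prefs)))
  ki <- 1L
  for (s in seq_len(n_steps)) {
    state <- rivalry_step(state, drive, L, params)
    if (ki <= n_keep && s == keep[ki]) {
      Xs[ki, ] <- state$X
      As[ki, ] <- state$A
      ki <- ki + 1L
    }
  }
  tgrid <- keep * params$dt

  i_delta <- which.min(abs(prefs - stimulus$slant_delta))
  i_chi <- which.min(abs(prefs - stimulus$slant_chi))
  structure(
    list(t = tgrid, X = Xs, A = As, prefs_deg = rad2deg(prefs),
         drive = drive, i_delta = i_delta, i_chi = i_chi,
         stimulus = stimulus, params = params, bimodal_drive = drv_full$bimodal),
    class = "rivalry_trajectory"
  )
}

# raw (signed) output profile for exact rates
noise_free_profile <- function(stimulus, config) {
  prefs <- preferred_slants(config)
  fd <- unimodal_rates(stimulus$slant_delta, stimulus$A_delta, config, prefs)
  fc <- unimodal_rates(stimulus$slant_chi, stimulus$A_chi, config, prefs)
  readout_output(combine_cues(fd, fc), build_readout(config))
}

#' @export
print.rivalry_trajectory <- function(x, ...) {
  d <- dominance_labels(x)
  sw <- dominance_switches(x)
  cat(sprintf("<rivalry_trajectory> T = %g (%d samples), %d switches\n",
              max(x$t), length(x$t), sw))
  invisible(x)
}

#' Dominance labels along a trajectory
#'
#' A percept dominates at a time point when its cue-consistent activity
#' exceeds the competitor's by `threshold_ratio`; other points are "mixed".
#'
#' @param trajectory A `rivalry_trajectory`.
#' @param threshold_ratio Dominance ratio criterion (> 1).
#' @return Tibble `t`, `label` (factor: "disparity", "texture", "mixed").
#' @export
dominance_labels <- function(trajectory, threshold_ratio = 1.5) {
  xd <- pmax(trajectory$X[, trajectory$i_delta], 0)
  xc <- pmax(trajectory$X[, trajectory$i_chi], 0)
  lab <- rep("mixed", length(xd))
  lab[xd > threshold_ratio * xc] <- "disparity"
  lab[xc > threshold_ratio * xd] <- "texture"
  tibble::tibble(t = trajectory$t, label = lab)
}

#' Dominance episodes and their durations
#'
#' Collapses the dominance labels into debounced episodes: runs of a single
#' percept lasting at least `min_duration` (default one activity time
#' constant). Mixed periods separate but do not count as episodes.
#'
#' @inheritParams dominance_labels
#' @param min_duration Minimum episode length (same time unit as `tau`).
#' @return Tibble with `percept`, `start`, `end`, `duration`, and
#'   `duration_tauA` (duration in units of the adaptation time constant).
#'   Zero rows when the trajectory never alternates or never reaches
#'   dominance.
#' @export
dominance_durations <- function(trajectory, threshold_ratio = 1.5,
                                min_duration = NULL) {
  if (is.null(min_duration)) min_duration <- trajectory$params$tau
  lab <- dominance_labels(trajectory, threshold_ratio)
  r <- rle(lab$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt_samp <- if (length(lab$t) > 1) diff(lab$t[1:2]) else 0
  out <- tibble::tibble(
    percept = r$values,
    start = lab$t[starts],
    end = lab$t[ends],
    duration = r$lengths * dt_samp
  )
  out <- out[out$percept != "mixed" & out$duration >= min_duration, ]
  # merge consecutive same-percept episodes separated only by mixed gaps
  if (nrow(out) > 1) {
    keep <- c(TRUE, out$percept[-1] != out$percept[-nrow(out)])
    grp <- cumsum(keep)
    out <- dplyr::summarise(
      dplyr::group_by(out, grp2 = grp),
      percept = dplyr::first(.data$percept),
      start = min(.data$start), end = max(.data$end),
      duration = sum(.data$duration), .groups = "drop"
    )[, c("percept", "start", "end", "duration")]
  }
  out$duration_tauA <- out$duration / trajectory$params$tau_A
  out
}

#' Number of dominance switches
#'
#' @inheritParams dominance_durations
#' @return Integer count of transitions between the two percepts' episodes.
#' @export
dominance_switches <- function(trajectory, threshold_ratio = 1.5,
                               min_duration = NULL) {
  ep <- dominance_durations(trajectory, threshold_ratio, min_duration)
  if (nrow(ep) < 2) return(0L)
  sum(ep$percept[-1] != ep$percept[-nrow(ep)])
}

#' Bistability index
#'
#' The difference (degrees) between the two cue-consistent slant estimates an
#' observer experiences. Under fusion there is a single percept and the index
#' is zero; once rivalry sets in, the observer has access to both
#' interpretations and the index approaches the cue conflict.
#'
#' For a single trajectory the index is the absolute difference between the
#' mean decoded slants during the two percepts' dominance episodes (zero if
#' fewer than one episode of each percept). `bistability_sweep()` maps the
#' index over a set of conflicts.
#'
#' @inheritParams dominance_durations
#' @return Scalar index in degrees.
#' @export
bistability_index <- function(trajectory, threshold_ratio = 1.5,
                              min_duration = NULL) {
  ep <- dominance_durations(trajectory, threshold_ratio, min_duration)
  if (length(unique(ep$percept)) < 2) return(0)
  est <- vapply(split(ep, ep$percept), function(e) {
    idx <- which(trajectory$t >= e$start[1] & trajectory$t <= e$end[1])
    # decoded slant during the first episode of this percept
    mean(trajectory$prefs_deg[max.col(pmax(trajectory$X[idx, , drop = FALSE], 0),
                                      ties.method = "first")])
  }, numeric(1))
  abs(diff(range(est)))
}

#' @rdname bistability_index
#' @param conflicts_deg Conflicts to test (degrees).
#' @param config A [model_config()].
#' @param params A [rivalry_params()]; a distinct seed is derived per
#'   conflict.
#' @param A_delta,A_chi Cue intensities (equal by default: the rivalry
#'   regime).
#' @return `bistability_sweep()`: tibble `conflict_deg`, `n_switches`,
#'   `bistability_deg`.
#' @export
bistability_sweep <- function(conflicts_deg, config = model_config(),
                              params = rivalry_params(),
                              A_delta = 1, A_chi = 1) {
  purrr::map_dfr(conflicts_deg, function(d) {
    p <- params
    p$seed <- params$seed + round(d)
    traj <- simulate_rivalry(
      slant_stimulus(-d / 2, d / 2, A_delta, A_chi), config, p)
    tibble::tibble(conflict_deg = d,
                   n_switches = dominance_switches(traj),
                   bistability_deg = bistability_index(traj))
  })
}
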