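#' Generate a synthetic observer cohort
#'
#' Builds a cohort in which a latent suppressive-gain trait (`beta_true`)
#' drives behaviour through the population model, and a noisy linear
#' transform of the trait plays the role of a neurochemical measurement
#' (`gaba_like`, arbitrary institutional units). Each observer's sensitivity
#' in the four standard conditions (single disparity, single texture,
#' congruent, incongruent) is computed from the model, converted to
#' behavioural units (calibrated so a typical observer's disparity
#' sensitivity is 0.16 per degree), and turned into 2IFC trial tables via a
#' Gaussian observer. By construction the trait is linked to incongruent-cue
#' sensitivity only, so the full pipeline (psychometric fitting + robust
#' correlation) should recover a strong trait-incongruent correlation and a
#' null trait-congruent correlation.
#'
#' @param n_observers Number of observers (>= 4).
#' @param trait_noise_sd SD of the noise on the trait-to-measurement mapping.
#' @param trials_per_condition 2IFC trials per condition (split over 8 test
#'   levels).
#' @param seed Integer seed.
#' @param config A [model_config()].
#' @param beta_mean,beta_sd Population distribution of the trait (clipped to
#'   `[0, 1]`).
#' @param intensity_sd Per-observer cue-intensity jitter (absolute).
#' @return Object of class `synthetic_cohort`: list with `traits` (one row
#'   per observer: `observer_id`, `beta_true`, `gaba_like`, true
#'   per-condition sensitivities) and `trials` (all trial tables,
#'   [simulate_2ifc()] schema plus `observer_id`).
#' @export
#' @examples
#' \donttest{
#' coh <- generate_cohort(6, trials_per_condition = 80, seed = 1)
#' nrow(coh$traits)
#' }
generate_cohort <- function(n_observers = 18L, trait_noise_sd = 0.1,
                            trials_per_condition = 400L, seed = 1L,
                            config = model_config(), beta_mean = 0.75,
                            beta_sd = 0.1, intensity_sd = 0.1) {
  n_observers <- as.integer(n_observers)
  if (n_observers < 4L) stop("`n_observers` must be >= 4", call. = FALSE)
  set.seed(seed)
  n_per_level <- max(1L, round(trials_per_condition / 8))

  # behavioural calibration: typical disparity single-cue sensitivity
  cal_cfg <- config
  cal_cfg$beta <- beta_mean
  cal <- 0.16 / decode_trials(slant_stimulus(30, 30, 1, 0), cal_cfg,
                              exact = TRUE)$sensitivity

  conditions <- function(A_d, A_t, A_ci) list(
    single_disparity = slant_stimulus(30, 30, A_d, 0),
    single_texture = slant_stimulus(30, 30, 0, A_t),
    congruent = slant_stimulus(30, 30, A_d, A_t),
    incongruent = slant_stimulus(20, 50, A_d, A_ci)
  )

  traits <- list()
  trials <- list()
  for (i in seq_len(n_observers)) {
    beta <- min(max(stats::rnorm(1, beta_mean, beta_sd), 0), 1)
    gaba <- 1 + 2 * beta + stats::rnorm(1, 0, trait_noise_sd)
    cfg <- config
    cfg$beta <- beta
    cfg$seed <- NULL
    jit <- function(A) max(stats::rnorm(1, A, intensity_sd), 0.01)
    cond <- conditions(jit(1), jit(1), jit(4))
    sens <- vapply(cond, function(st)
      cal * mean(decode_trials(st, cfg)$sensitivity, na.rm = TRUE),
      numeric(1))
    obs_id <- sprintf("obs%02d", i)
    traits[[i]] <- tibble::tibble(
      observer_id = obs_id, beta_true = beta, gaba_like = gaba,
      sens_single_disparity = sens[["single_disparity"]],
      sens_single_texture = sens[["single_texture"]],
      sens_congruent = sens[["congruent"]],
      sens_incongruent = sens[["incongruent"]]
    )
    trials[[i]] <- purrr::map_dfr(names(cond), function(nm) {
      sigma <- sensitivity_to_sigma(sens[[nm]])
      # test range calibrated per observer and condition (as a pilot /
      # familiarisation stage would), spanning ~0.5-3 discrimination SDs
      span <- sigma * sqrt(2) * c(0.55, 1.1, 1.9, 3)
      tt <- simulate_2ifc(sigma, reference = 40,
                          test_levels = 40 + c(-rev(span), span),
                          n_per_level = n_per_level, condition_id = nm)
      tt$observer_id <- obs_id
      tt
    })
  }
  structure(
    list(traits = dplyr::bind_rows(traits), trials = dplyr::bind_rows(trials),
         seed = seed, trait_noise_sd = trait_noise_sd,
         trials_per_condition = 8L * n_per_level),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d observers, %d trials/condition\n",
              nrow(x$traits), x$trials_per_condition))
  invisible(x)
}

#' Recover per-observer sensitivities and trait correlations from a cohort
#'
#' Runs the analysis pipeline end to end: fits a psychometric function to
#' each observer x condition trial table, takes sensitivity as the reciprocal
#' j.n.d., and correlates the neurochemical-like trait measurement with the
#' recovered sensitivities per condition using [robust_pearson()].
#'
#' @param cohort A `synthetic_cohort`.
#' @return List with `fits` (observer x condition tibble of recovered `pse`,
#'   `jnd`, `sensitivity`) and `correlations` (per condition: robust Pearson
#'   r, p, CI, outliers; plus Spearman rank correlation).
#' @export
analyze_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  fits <- cohort$trials |>
    dplyr::group_by(.data$observer_id, .data$condition_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_psychometric(d)
      tibble::tibble(pse = f$pse, jnd = f$jnd, sensitivity = f$sensitivity,
                     lapse = f$lapse, flagged = length(f$flags) > 0)
    }) |>
    dplyr::ungroup()
  wide <- dplyr::left_join(cohort$traits, fits,
                           by = "observer_id")
  cors <- purrr::map_dfr(unique(fits$condition_id), function(cid) {
    d <- wide[wide$condition_id == cid, ]
    rc <- robust_pearson(d$gaba_like, d$sensitivity)
    tibble::tibble(
      condition = cid, n = rc$n_used, r = rc$r, p = rc$p,
      ci_lo = rc$conf_int[1], ci_hi = rc$conf_int[2],
      n_outliers = length(rc$outlier_idx),
      rho_spearman = stats::cor(d$gaba_like, d$sensitivity,
                                method = "spearman")
    )
  })
  list(fits = fits, correlations = cors)
}

#' Export / read a cohort as a CSV bundle
#'
#' Writes `traits.csv` and `trials.csv` into a directory; `read_cohort()`
#' reconstructs the cohort losslessly (up to the stored metadata).
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Directory (created if missing).
#' @return `export_cohort()`: the paths written, invisibly. `read_cohort()`:
#'   a `synthetic_cohort`.
#' @export
export_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  traits_path <- file.path(path, "traits.csv")
  trials_path <- file.path(path, "trials.csv")
  readr::write_csv(cohort$traits, traits_path)
  readr::write_csv(cohort$trials, trials_path)
  invisible(c(traits = traits_path, trials = trials_path))
}

#' @rdname export_cohort
#' @export
read_cohort <- function(path) {
  traits <- readr::read_csv(file.path(path, "traits.csv"),
                            show_col_types = FALSE)
  trials <- readr::read_csv(file.path(path, "trials.csv"),
                            show_col_types = FALSE)
  structure(
    list(traits = traits, trials = trials, seed = NA_integer_,
         trait_noise_sd = NA_real_,
         trials_per_condition = if (nrow(trials))
           nrow(trials) / max(1, nrow(traits) * length(unique(trials$condition_id)))
         else 0L),
    class = "synthetic_cohort"
  )
}
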