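#' Simulate a two-interval forced-choice session
#'
#' Generates trial-level responses for a 2IFC slant-discrimination task with
#' the method of constant stimuli. The observer can be given as a single
#' internal-noise SD (degrees): each interval's slant is perturbed by
#' independent Gaussian noise and the observer reports the interval that
#' looks more slanted, so the probability of choosing the test is
#' `pnorm((test - reference) / (sigma * sqrt(2)))`. The `sqrt(2)` in the
#' sensitivity convention of [sigma_to_sensitivity()] therefore emerges from
#' the task rather than being inserted. Alternatively pass a function
#' `p_choose_test(test, reference)` for a custom observer.
#'
#' @param observer Positive scalar (internal SD, degrees) or a function of
#'   `(test, reference)` returning choice probabilities.
#' @param reference Reference slant (degrees).
#' @param test_levels Test slants (degrees); should bracket the reference.
#' @param n_per_level Trials per test level.
#' @param condition_id Label stored with the trials.
#' @param seed Optional integer seed.
#' @return Tibble (a trial table): `condition_id`, `reference_level`,
#'   `test_level`, `response` (1 = chose test).
#' @export
#' @examples
#' tt <- simulate_2ifc(5, 40, seq(20, 60, by = 5), 20, seed = 1)
#' mean(tt$response[tt$test_level == 40])  # ~0.5
simulate_2ifc <- function(observer, reference, test_levels, n_per_level,
                          condition_id = "condition1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_fun <- if (is.function(observer)) {
    observer
  } else {
    if (!is.numeric(observer) || observer <= 0)
      stop("`observer` must be a positive SD or a function", call. = FALSE)
    function(test, reference) stats::pnorm((test - reference) /
                                             (observer * sqrt(2)))
  }
  levels <- rep(test_levels, each = n_per_level)
  p <- p_fun(levels, reference)
  tibble::tibble(
    condition_id = condition_id,
    reference_level = reference,
    test_level = levels,
    response = stats::rbinom(length(levels), 1, p)
  )
}

#' Fit a psychometric function to 2IFC trial data
#'
#' Maximum-likelihood fit of a cumulative Gaussian with a lapse parameter,
#' `P(chose test) = lapse + (1 - 2*lapse) * pnorm(x, pse, sigma)`.
#' The point of subjective equality (PSE) is the 50% level, the
#' just-noticeable difference is the 50-84% level difference (one SD of the
#' underlying Gaussian), and sensitivity is the reciprocal of the j.n.d.
#'
#' @param table Trial table as produced by [simulate_2ifc()]: columns
#'   `test_level` and `response` (binary); other columns are ignored.
#' @param lapse_max Upper bound on the lapse rate.
#' @param jnd_convention Multiple of the fitted SD that defines the j.n.d.
#'   (default 1, the 50-84% convention).
#' @return Object of class `psychometric_fit`: `pse`, `jnd`, `sensitivity`,
#'   `lapse`, `sigma`, `loglik`, `deviance`, `n_trials`, `flags` (character;
#'   "jnd_at_lower_bound" marks step-function data).
#' @export
#' @examples
#' tt <- simulate_2ifc(5, 40, seq(20, 60, by = 5), 50, seed = 1)
#' fit <- fit_psychometric(tt)
#' c(fit$pse, fit$jnd)
fit_psychometric <- function(table, lapse_max = 0.1, jnd_convention = 1) {
  x <- table$test_level
  y <- table$response
  if (length(unique(x)) < 4L)
    stop("need at least 4 distinct test levels", call. = FALSE)
  if (length(y) < 10L) stop("need at least 10 trials", call. = FALSE)
  if (!all(y %in% 0:1)) stop("responses must be binary", call. = FALSE)

  rng <- diff(range(x))
  sig_lo <- 1e-3 * rng
  sig_hi <- 10 * rng
  # aggregate to binomial counts per level: the likelihood only depends on
  # per-level successes, and this keeps fits cheap for large sessions
  lev <- sort(unique(x))
  n_k <- vapply(lev, function(l) sum(x == l), numeric(1))
  y_k <- vapply(lev, function(l) sum(y[x == l]), numeric(1))
  nll <- function(par) {
    p <- par[3] + (1 - 2 * par[3]) * stats::pnorm(lev, par[1], exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y_k * log(p) + (n_k - y_k) * log(1 - p))
  }
  start <- c(stats::median(x), log(rng / 4), 0.01)
  fit <- stats::optim(start, nll, method = "L-BFGS-B",
                      lower = c(min(x) - rng, log(sig_lo), 0),
                      upper = c(max(x) + rng, log(sig_hi), lapse_max))
  sigma <- exp(fit$par[2])
  flags <- character()
  # level-independence check: the psychometric fit must beat the
  # intercept-only model by a likelihood-ratio criterion
  p0 <- pmin(pmax(mean(y), 1e-12), 1 - 1e-12)
  ll0 <- sum(y_k * log(p0) + (n_k - y_k) * log(1 - p0))
  if (sigma >= sig_hi * 0.99 || 2 * (-fit$value - ll0) < stats::qchisq(0.99, 2)) {
    stop("degenerate fit: responses do not depend on the stimulus level ",
         "(slope indistinguishable from zero)", call. = FALSE)
  }
  if (sigma <= sig_lo * 1.01) flags <- c(flags, "jnd_at_lower_bound")
  if (fit$par[1] <= min(x) - rng * 0.99 || fit$par[1] >= max(x) + rng * 0.99)
    flags <- c(flags, "pse_at_bound")

  # saturated-model deviance over levels
  p_hat <- pmin(pmax(y_k / n_k, 1e-12), 1 - 1e-12)
  ll_sat <- sum(n_k * (p_hat * log(p_hat) + (1 - p_hat) * log(1 - p_hat)))
  jnd <- jnd_convention * sigma
  structure(
    list(pse = fit$par[1], jnd = jnd, sensitivity = 1 / jnd,
         lapse = fit$par[3], sigma = sigma,
         loglik = -fit$value, deviance = 2 * (ll_sat - (-fit$value)),
         n_trials = length(y), n_levels = length(unique(x)),
         flags = flags),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> PSE %.2f deg, j.n.d. %.2f deg (sensitivity %.3f/deg), lapse %.3f%s\n",
    x$pse, x$jnd, x$sensitivity, x$lapse,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return One row per parameter (`pse`, `jnd`, `sensitivity`, `lapse`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse", "jnd", "sensitivity", "lapse"),
    estimate = c(x$pse, x$jnd, x$sensitivity, x$lapse)
  )
}

#' @rdname tidy.psychometric_fit
#' @return `glance()`: one-row tibble with fit diagnostics.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, deviance = x$deviance,
    n_trials = x$n_trials, n_levels = x$n_levels,
    flagged = length(x$flags) > 0
  )
}

#' Default-prior Bayes factor from a t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor (alternative over null) for a
#' one-sample or paired t test, computed by numerical integration over the
#' Cauchy prior scale on effect size (`r_scale`, default `sqrt(2)/2`).
#' Values above 1 favour the alternative.
#'
#' @param t_value Observed t statistic.
#' @param n Sample size (pairs for a paired test; >= 3).
#' @param r_scale Cauchy prior scale.
#' @return Scalar Bayes factor (BF10), as an odds ratio.
#' @export
#' @examples
#' bayes_factor_from_t(0, 20) < 1
bayes_factor_from_t <- function(t_value, n, r_scale = sqrt(2) / 2) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("`n` must be >= 3", call. = FALSE)
  nu <- n - 1
  lik <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t_value^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      # inverse-gamma(1/2, r^2/2) prior density on g
      (r_scale^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) *
      exp(-r_scale^2 / (2 * g))
  }
  num <- stats::integrate(lik, 0, Inf, rel.tol = 1e-9)$value
  den <- (1 + t_value^2 / nu)^(-(nu + 1) / 2)
  num / den
}

#' Cap combined reliabilities at the quadratic-sum bound
#'
#' Optimal fusion of two independent cues cannot exceed the quadratic sum of
#' the single-cue reliabilities; averaged data points above that bound
#' (typically inflated by latent cues in nominally single-cue stimuli) are
#' replaced by it.
#'
#' @param combined Combined-cue reliabilities (>= 0).
#' @param single1,single2 Matched single-cue reliabilities (>= 0; recycled if
#'   scalar).
#' @return `combined`, elementwise capped at `sqrt(single1^2 + single2^2)`.
#' @export
#' @examples
#' cap_quadratic(c(1.6, 1.2), 1, 1)   # c(sqrt(2), 1.2)
cap_quadratic <- function(combined, single1, single2) {
  if (any(c(combined, single1, single2) < 0))
    stop("reliabilities must be >= 0", call. = FALSE)
  pmin(combined, sqrt(single1^2 + single2^2))
}

#' Outlier screen in log space
#'
#' Log-transforms positive values, removes points more than `n_sd` standard
#' deviations from the mean, and back-transforms. With fewer than 3 values
#' the SD is unstable, so nothing is removed (with a warning).
#'
#' @param values Positive numeric vector.
#' @param n_sd Removal threshold in SD units (default 3).
#' @return List with `kept` (original order preserved), `removed`, and
#'   `removed_idx`.
#' @export
#' @examples
#' screen_outliers_log3sd(c(rep(1, 30), 1e6))$removed
screen_outliers_log3sd <- function(values, n_sd = 3) {
  if (any(values <= 0)) stop("values must be > 0 (log transform)", call. = FALSE)
  if (length(values) < 3) {
    warning("fewer than 3 values: SD is unstable, nothing removed",
            call. = FALSE)
    return(list(kept = values, removed = numeric(0), removed_idx = integer(0)))
  }
  lv <- log(values)
  s <- stats::sd(lv)
  if (s == 0)
    return(list(kept = values, removed = numeric(0), removed_idx = integer(0)))
  z <- (lv - mean(lv)) / s
  out <- abs(z) > n_sd
  list(kept = values[!out], removed = values[out], removed_idx = which(out))
}

#' Robust Pearson correlation with bivariate boxplot-rule outlier rejection
#'
#' Rejects bivariate outliers with the boxplot rule: a point is an outlier
#' when either of its coordinates falls outside the 1.5 IQR fences of that
#' variable. The Pearson correlation is then computed on the kept points with
#' a t-based p value and a bootstrap percentile confidence interval.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_boot Bootstrap replicates for the CI.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return Object of class `robust_cor`: `r`, `t`, `p`, `conf_int`,
#'   `n_used`, `outlier_idx`.
#' @export
#' @examples
#' x <- 1:20
#' robust_pearson(x, 2 * x + c(rep(0, 19), 50))$outlier_idx
robust_pearson <- function(x, y, n_boot = 2000, conf = 0.95, seed = 1L) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined", call. = FALSE)
  fence <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.75))
    iqr <- q[2] - q[1]
    v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
  }
  out <- fence(x) | fence(y)
  keep <- which(!out)
  if (length(keep) < 4)
    stop("fewer than 4 points remain after outlier rejection", call. = FALSE)
  xk <- x[keep]
  yk <- y[keep]
  n <- length(keep)
  r <- stats::cor(xk, yk)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    if (stats::sd(xk[idx]) == 0 || stats::sd(yk[idx]) == 0) NA_real_
    else stats::cor(xk[idx], yk[idx])
  })
  ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE)
  structure(
    list(r = r, t = tval, p = p, conf_int = unname(ci), conf = conf,
         n_used = n, outlier_idx = which(ok)[which(out)]),
    class = "robust_cor"
  )
}

#' @export
print.robust_cor <- function(x, ...) {
  cat(sprintf(
    "<robust_cor> r = %.3f (n = %d, p = %.3g, %d%% CI [%.3f, %.3f]), %d outlier(s) rejected\n",
    x$r, x$n_used, x$p, round(100 * x$conf), x$conf_int[1], x$conf_int[2],
    length(x$outlier_idx)))
  invisible(x)
}

#' @rdname tidy.psychometric_fit
#' @export
tidy.robust_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, statistic = x$t, p.value = x$p,
                 conf.low = x$conf_int[1], conf.high = x$conf_int[2],
                 n = x$n_used, n_outliers = length(x$outlier_idx))
}

#' Cerebrospinal-fluid tissue correction for MRS concentrations
#'
#' Corrects a measured metabolite concentration for the fraction of the
#' spectroscopy voxel occupied by CSF: `C / (f_GM + f_WM)`.
#'
#' @param C_meas Measured concentration.
#' @param f_GM,f_WM Grey- and white-matter volume fractions; their sum must
#'   lie in (0, 1].
#' @return Corrected concentration (>= measured; equal iff the fractions sum
#'   to 1).
#' @export
#' @examples
#' tissue_correct(1, 0.4, 0.4)  # 1.25
tissue_correct <- function(C_meas, f_GM, f_WM) {
  s <- f_GM + f_WM
  if (any(s <= 0) || any(s > 1))
    stop("f_GM + f_WM must lie in (0, 1]", call. = FALSE)
  C_meas / s
}
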