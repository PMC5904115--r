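test_that("the 2IFC simulator is unbiased at the reference and reproducible", {
  tt <- simulate_2ifc(5, 40, rep(40, 1), 4000, seed = 1)
  expect_lt(abs(mean(tt$response) - 0.5), 0.03)

  a <- simulate_2ifc(5, 40, seq(20, 60, 5), 10, seed = 3)
  b <- simulate_2ifc(5, 40, seq(20, 60, 5), 10, seed = 3)
  expect_identical(a, b)
})

test_that("psychometric fitting recovers generating parameters", {
  # observer defined directly by its psychometric function: PSE 40, SD 5
  obs <- function(test, reference) stats::pnorm(test, 40, 5)
  tt <- simulate_2ifc(obs, 40, 40 + c(-12, -8, -5, -2.5, 2.5, 5, 8, 12),
                      500, seed = 2)
  fit <- fit_psychometric(tt)
  expect_lt(abs(fit$pse - 40), 0.5)
  expect_lt(abs(fit$jnd - 5), 0.5)
  expect_equal(fit$sensitivity, 1 / fit$jnd, tolerance = 1e-12)
  expect_lte(fit$lapse, 0.1)
})

test_that("parameter recovery holds across a grid of generating values", {
  for (case in list(c(pse = 35, sd = 3, seed = 4),
                    c(pse = 45, sd = 8, seed = 5),
                    c(pse = 40, sd = 5, seed = 6))) {
    obs <- function(test, reference) stats::pnorm(test, case["pse"], case["sd"])
    span <- case["sd"] * c(0.5, 1, 1.8, 2.8)
    tt <- simulate_2ifc(obs, case["pse"],
                        case["pse"] + c(-rev(span), span), 150,
                        seed = case["seed"])
    fit <- fit_psychometric(tt)
    expect_lt(abs(fit$pse - case["pse"]), 0.1 * case["sd"] * 3)
    expect_lt(abs(fit$jnd - case["sd"]) / case["sd"], 0.15)
  }
})

test_that("the sqrt(2) sensitivity convention emerges from the 2IFC task", {
  sigma <- 4
  tt <- simulate_2ifc(sigma, 40, 40 + c(-15, -10, -6, -3, 3, 6, 10, 15),
                      400, seed = 7)
  fit <- fit_psychometric(tt)
  expect_lt(abs(fit$sensitivity - sigma_to_sensitivity(sigma)) /
              sigma_to_sensitivity(sigma), 0.1)
})

test_that("degenerate psychometric data are rejected or flagged", {
  set.seed(1)
  lev <- rep(seq(20, 60, 5), each = 20)
  flat <- tibble::tibble(test_level = lev, response = rbinom(length(lev), 1, 0.5))
  expect_error(fit_psychometric(flat), "degenerate")

  step <- tibble::tibble(test_level = lev, response = as.integer(lev > 40))
  fit <- fit_psychometric(step)
  expect_true("jnd_at_lower_bound" %in% fit$flags)

  expect_error(fit_psychometric(tibble::tibble(test_level = c(1, 2, 3),
                                               response = c(0, 1, 1))),
               "4 distinct")
})

test_that("tidy and glance summarise psychometric fits", {
  tt <- simulate_2ifc(5, 40, seq(25, 55, 5), 60, seed = 9)
  fit <- fit_psychometric(tt)
  td <- tidy(fit)
  expect_equal(td$term, c("pse", "jnd", "sensitivity", "lapse"))
  gl <- glance(fit)
  expect_equal(gl$n_trials, nrow(tt))
})

test_that("the default-prior Bayes factor behaves and matches an independent integration", {
  expect_lt(bayes_factor_from_t(0, 20), 1)
  bfs <- vapply(c(0, 1, 2, 3, 4), bayes_factor_from_t, numeric(1), n = 15)
  expect_true(all(diff(bfs) > 0))
  expect_error(bayes_factor_from_t(2, 2), ">= 3")

  # frozen values from a Monte-Carlo integration over the prior on effect
  # size (2e6 draws of g from its inverse-gamma prior)
  expect_equal(bayes_factor_from_t(2, 15), 1.25265, tolerance = 0.005)
  expect_equal(bayes_factor_from_t(3, 30), 7.49578, tolerance = 0.005)
  expect_equal(bayes_factor_from_t(0, 30), 0.19441, tolerance = 0.005)
})

test_that("quadratic capping replaces only values above the bound", {
  expect_equal(cap_quadratic(c(1.6, 1.2, sqrt(2)), 1, 1),
               c(sqrt(2), 1.2, sqrt(2)))
  expect_equal(cap_quadratic(cap_quadratic(1.9, 1, 1), 1, 1),
               cap_quadratic(1.9, 1, 1))
  expect_error(cap_quadratic(-1, 1, 1), ">= 0")
})

test_that("log-space outlier screening removes gross outliers only", {
  same <- screen_outliers_log3sd(rep(2.5, 10))
  expect_length(same$removed, 0)

  set.seed(2)
  v <- c(rlnorm(30, 0, 0.1), 1e6)
  sc <- screen_outliers_log3sd(v)
  expect_equal(sc$removed_idx, 31L)
  # direct z-score oracle in log space
  z <- (log(v) - mean(log(v))) / sd(log(v))
  expect_equal(sc$removed_idx, which(abs(z) > 3))
  # a second pass on the kept values removes nothing here
  expect_length(screen_outliers_log3sd(sc$kept)$removed, 0)

  expect_warning(screen_outliers_log3sd(c(1, 2)), "unstable")
  expect_error(screen_outliers_log3sd(c(1, -1, 2)), "> 0")
})

test_that("robust correlation rejects gross bivariate outliers", {
  x <- 1:20
  clean <- robust_pearson(x, 2 * x)
  expect_equal(clean$r, 1, tolerance = 1e-12)

  y <- 2 * x
  y[20] <- 150
  rc <- robust_pearson(x, y)
  expect_equal(rc$outlier_idx, 20L)
  expect_gt(rc$r, 0.999)
  expect_true(rc$conf_int[1] <= rc$r && rc$r <= rc$conf_int[2])

  expect_error(robust_pearson(rep(1, 10), rnorm(10)), "constant")
})

test_that("tissue correction divides by the brain-tissue fraction", {
  expect_equal(tissue_correct(1, 0.5, 0.5), 1)
  expect_equal(tissue_correct(1, 0.4, 0.4), 1.25)
  expect_gte(tissue_correct(2, 0.3, 0.5), 2)
  expect_error(tissue_correct(1, 0, 0), "0, 1")
  expect_error(tissue_correct(1, 0.7, 0.7), "0, 1")
})
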