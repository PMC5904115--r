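#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a conflict sweep
#'
#' Bias and relative reliability as a function of cue conflict — the robust
#' "rise-then-revert" signature of the suppressive readout.
#'
#' @param object A `conflict_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conflict_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("conflict_deg", "bias_deg", "rel_reliability")],
    -"conflict_deg", names_to = "measure")
  d$measure <- factor(d$measure, c("bias_deg", "rel_reliability"),
                      c("bias (deg)", "reliability / reliable single cue"))
  ggplot2::ggplot(d, ggplot2::aes(.data$conflict_deg, .data$value)) +
    ggplot2::geom_hline(
      data = data.frame(measure = levels(d$measure), y = c(0, 1)),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cue conflict (deg)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a suppression sweep
#'
#' Scatter of per-simulation sensitivity against the sampled suppressive gain
#' for the incongruent, congruent and single-cue conditions.
#'
#' @param object A `suppression_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.suppression_sweep <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$simulations[, c("beta", "sens_incongruent", "sens_congruent",
                           "sens_single_disparity")],
    -"beta", names_to = "condition", values_to = "sensitivity")
  d$condition <- sub("sens_", "", d$condition)
  ggplot2::ggplot(d, ggplot2::aes(.data$beta, .data$sensitivity)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~condition, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = expression(beta ~ "(suppressive gain)"),
                  y = "model sensitivity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a rivalry trajectory
#'
#' Activity of the two cue-consistent output units over time, with dominance
#' episodes shaded.
#'
#' @param object A `rivalry_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rivalry_trajectory <- function(object, ...) {
  d <- tibble::tibble(
    t = rep(object$t, 2),
    percept = rep(c("disparity", "texture"), each = length(object$t)),
    X = c(pmax(object$X[, object$i_delta], 0),
          pmax(object$X[, object$i_chi], 0))
  )
  ep <- dominance_durations(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$X,
                                       colour = .data$percept))
  if (nrow(ep))
    p <- p + ggplot2::geom_rect(
      data = ep, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$percept),
      alpha = 0.15)
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (tau units)", y = "output activity") +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit over its data
#'
#' @param object A `psychometric_fit`.
#' @param table The trial table the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psychometric_fit <- function(object, table, ...) {
  agg <- dplyr::summarise(dplyr::group_by(table, .data$test_level),
                          p = mean(.data$response), n = dplyr::n(),
                          .groups = "drop")
  grid <- tibble::tibble(
    test_level = seq(min(agg$test_level), max(agg$test_level),
                     length.out = 200))
  grid$p <- object$lapse + (1 - 2 * object$lapse) *
    stats::pnorm(grid$test_level, object$pse, object$sigma)
  ggplot2::ggplot(agg, ggplot2::aes(.data$test_level, .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$pse, linetype = 2,
                        colour = "grey50") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "test slant (deg)", y = "P(chose test)") +
    ggplot2::theme_minimal()
}
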