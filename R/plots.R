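#' Plot a fitted discounting curve
#'
#' Indifference points with the fitted hyperbola overlaid.
#'
#' @param object A `mazur_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mazur_fit
#' @export
autoplot.mazur_fit <- function(object, ...) {
  grid <- tibble::tibble(delay_s = seq(0, max(object$data$delay_s), length.out = 200))
  grid$fitted <- predict(object, grid$delay_s)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$delay_s)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted), color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$indifference_point), size = 2) +
    ggplot2::labs(
      x = "Delay (s)", y = "Indifference point (pellets)",
      title = sprintf("Hyperbolic discounting fit, k = %.3g /s", object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot condition-averaged firing rates
#'
#' Mean z-scored rate (ribbon = +/- SEM) per choice condition over time,
#' with significant FDR-corrected timepoints marked below the traces.
#'
#' @param object A `condition_averages`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot condition_averages
#' @export
autoplot.condition_averages <- function(object, ...) {
  sig <- dplyr::filter(object$tests, .data$significant)
  ymin <- min(object$averages$mean - object$averages$sem)
  p <- ggplot2::ggplot(
    object$averages,
    ggplot2::aes(x = .data$time, y = .data$mean, color = .data$condition,
                 fill = .data$condition)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.2, color = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Time from choice (s)", y = "z-scored firing rate") +
    ggplot2::theme_minimal()
  if (nrow(sig)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(sig, y = ymin - 0.05 * abs(ymin)),
      ggplot2::aes(x = .data$time, y = .data$y, shape = .data$contrast),
      inherit.aes = FALSE, size = 1
    )
  }
  p
}

#' Plot state-space trajectories
#'
#' Each leading principal component's score over time bins, one panel per
#' component, colored by trial type.
#'
#' @param object A `state_space`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_space
#' @export
autoplot.state_space <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$scores, dplyr::starts_with("PC"),
    names_to = "component", values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$bin, y = .data$score, color = .data$trial_type
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "Time bin", y = "PC score") +
    ggplot2::theme_minimal()
}

#' Plot trajectory distances per run type
#'
#' Per-bin Euclidean distance between the third- and fourth-trial
#' trajectories for every run type in the session.
#'
#' @param object A `session_distances`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot session_distances
#' @export
autoplot.session_distances <- function(object, ...) {
  ggplot2::ggplot(object$distances, ggplot2::aes(
    x = .data$time, y = .data$distance, color = .data$run_type
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Time from choice (s)", y = "Euclidean distance (top PCs)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
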