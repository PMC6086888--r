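#' Plot a simulated network trajectory
#'
#' Shows the activity of all four unit populations over time, one facet
#' per population, colored by option - the canonical view of the fast
#' transients, sustained plateaus and slow across-trial drift.
#'
#' @param object An `nn_trajectory` with recorded samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nn_trajectory <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(-"time", names_to = "unit",
                        values_to = "rate") |>
    tidyr::separate_wider_regex(
      "unit", c(population = ".*", "_", option = "[0-9]+")
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$rate,
                                     color = .data$option)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~population, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time", y = "activity (a.u.)",
                  color = "option") +
    ggplot2::theme_minimal()
}

#' Plot a fitted choice curve
#'
#' Per-level choice proportions (point size by trial count) with the
#' fitted sigmoid overlaid.
#'
#' @param object A `choice_curve_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.choice_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$levels$x), max(object$levels$x),
            length.out = 200)
  )
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$levels, ggplot2::aes(.data$x, .data$p)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$y),
                       color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "variable magnitude", y = "P(choose variable)",
      size = "trials",
      subtitle = sprintf("x50 = %.2f, slope = %.2f", object$x50, object$s)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a timescale sweep
#'
#' Model-behavior adaptation correlation as a function of the
#' slow/fast timescale ratio (log axis).
#'
#' @param object An `nn_tau_sweep` tibble from [tau_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nn_tau_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$ratio, .data$r)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "timescale ratio (tau_slow / tau_fast)",
                  y = "model-behavior correlation r") +
    ggplot2::theme_minimal()
}

#' Plot a shuffle null distribution
#'
#' Histogram of the null model-behavior correlations under the shuffle,
#' with the observed correlation marked.
#'
#' @param object An `nn_shuffle_null` from [shuffle_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nn_shuffle_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(r = object$null_r),
                  ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70",
                            color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_r,
                        color = "black", linewidth = 1) +
    ggplot2::labs(
      x = "null correlation r", y = "count",
      subtitle = sprintf("%s shuffle: observed r = %.3f, p = %.4g",
                         object$kind, object$observed_r, object$p)
    ) +
    ggplot2::theme_minimal()
}
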