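#' Plot a fitted psychometric curve
#'
#' Observed per-ITI fractions of long choices with the fitted
#' lapse-logistic curve and the category boundary.
#'
#' @param object A `psyfit` from [fit_psychometric()].
#' @param boundary_ms Vertical reference line (default 275 ms).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psyfit
#' @export
autoplot.psyfit <- function(object, boundary_ms = 275, ...) {
  grid <- tibble::tibble(
    iti_ms = seq(min(object$data$iti_ms), max(object$data$iti_ms),
                 length.out = 200)
  )
  grid$p <- predict(object, grid$iti_ms)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$iti_ms)) +
    ggplot2::geom_vline(xintercept = boundary_ms, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(y = .data$frac_long,
                                     size = .data$n_trials)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "inter-tone interval (ms)", y = "P(long choice)") +
    ggplot2::theme_minimal()
}

#' Win-stay vs lose-switch session scatter
#'
#' Each point is a session; the no-strategy point is (0.5, 0.5), the
#' diagonal marks equal win-stay and lose-switch probabilities.
#'
#' @param object A `wsls_result` from [wsls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wsls_result
#' @export
autoplot.wsls_result <- function(object, ...) {
  ggplot2::ggplot(object$sessions,
                  ggplot2::aes(x = .data$p_win_stay,
                               y = .data$p_lose_switch)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("point", x = 0.5, y = 0.5, shape = 3, size = 3,
                      colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "P(win-stay)", y = "P(lose-switch)") +
    ggplot2::theme_minimal()
}

#' Plot PSTH curves
#'
#' @param psth_tbl Output of [psth()].
#' @return A ggplot object (rate with SEM ribbon per condition).
#' @export
plot_psth <- function(psth_tbl) {
  ggplot2::ggplot(psth_tbl,
                  ggplot2::aes(x = .data$time_ms, y = .data$rate,
                               colour = .data$condition,
                               fill = .data$condition)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - .data$sem,
                                      ymax = .data$rate + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from event (ms)", y = "rate (spikes/s)") +
    ggplot2::theme_minimal()
}

#' Decoding performance by ensemble size
#'
#' Mean decoding performance per variable as a function of ensemble size,
#' for all ensembles and for the top-fraction most informative ones.
#'
#' @param object A `rank_result` from [rank_variables()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rank_result
#' @export
autoplot.rank_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$size, y = .data$mean_dp,
                               colour = .data$variable,
                               linetype = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ensemble size (neurons)",
                  y = "decoding performance") +
    ggplot2::theme_minimal()
}
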