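# ggplot2 methods for simulation objects.

#' Plot a tumor state on the lattice
#'
#' Tile plot of the occupied lattice sites colored by phenotype.
#'
#' @param state A [tumor_state()].
#' @return A ggplot object.
#' @export
plot_state <- function(state) {
  cells <- state$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$phenotype)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(S = "#D55E00", N = "#56B4E9"),
                               labels = c(S = "CSC", N = "nonstem")) +
    ggplot2::labs(x = "x (sites)", y = "y (sites)", fill = NULL,
                  title = sprintf("day %.0f: %d cells", state$time_h / 24,
                                  nrow(cells))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tumor_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("n_total", "n_csc"),
                              names_to = "series", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$n,
                                     color = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_manual(values = c(n_total = "black",
                                           n_csc = "#D55E00"),
                                labels = c(n_total = "all cells",
                                           n_csc = "CSC")) +
    ggplot2::labs(x = "day", y = "cells", color = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.growth_cohort <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$day, y = .data$mean_n)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_n - .data$sd_n, 0),
      ymax = .data$mean_n + .data$sd_n), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "mean cell count (+/- SD)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rt_course <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$day, y = .data$n_total,
                               color = .data$phase)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "cells (log scale)", color = "phase") +
    ggplot2::theme_minimal()
}
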