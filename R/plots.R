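#' Plot methods
#'
#' `autoplot()` methods for the main result types: species counts over time
#' for a simulation, power vs frequency for a spectrum (log-log), mean
#' population vs capacity with the fitted line for a sweep, and a snapshot
#' scatter of a population state.
#'
#' @param object An `ml_sim`, `ml_spectrum`, `capacity_sweep` or
#'   `population_state`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-mayleonard
NULL

#' @rdname autoplot-mayleonard
#' @export
autoplot.ml_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, c("n_A", "n_B", "n_C"),
                              names_to = "species", values_to = "n")
  long$species <- sub("n_", "", long$species)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$n,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(A = "#d73027", B = "#4575b4",
                                            C = "#fdae61")) +
    ggplot2::labs(x = "MC step", y = "individuals", colour = "species")
}

#' @rdname autoplot-mayleonard
#' @export
autoplot.ml_spectrum <- function(object, ...) {
  nz <- object[object$k > 0, , drop = FALSE]
  ggplot2::ggplot(nz, ggplot2::aes(x = .data$k, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "cycles per window", y = "mean squared amplitude")
}

#' @rdname autoplot-mayleonard
#' @export
autoplot.capacity_sweep <- function(object, ...) {
  fit <- fit_capacity_line(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$M, y = .data$mean_N)) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "grey50", linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_N - .data$stderr_N,
      ymax = .data$mean_N + .data$stderr_N)) +
    ggplot2::labs(x = "local carrying capacity M",
                  y = "mean total population")
}

#' @rdname autoplot-mayleonard
#' @export
autoplot.population_state <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$species)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c(A = "#d73027", B = "#4575b4",
                                            C = "#fdae61")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = "species")
}
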