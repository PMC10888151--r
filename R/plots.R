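# ggplot2 views of the three result types: trajectories, spectra, sweeps.

#' Plot a trajectory's process time courses
#'
#' @param object A `binding_trajectory`.
#' @param processes Columns to draw (default the main processes `p*`, `q*`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_trajectory <- function(object,
                                        processes = grep("^[pq]", names(object),
                                                         value = TRUE),
                                        ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(unclass_trajectory(object)),
                  "time", dplyr::all_of(processes)),
    -"time", names_to = "process", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$process)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (arb. u.)", y = "process value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.binding_trajectory <- function(x, ...) print(autoplot(x, ...))

#' Plot a normalized power spectrum
#'
#' @param object A `binding_spectrum`.
#' @param normalized Draw the normalized PSD (default) or the raw PSD.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_spectrum <- function(object, normalized = TRUE, ...) {
  ycol <- if (normalized) "normalized_psd" else "psd"
  ggplot2::ggplot(tibble::as_tibble(as.data.frame(object)),
                  ggplot2::aes(x = .data$frequency, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency (cycles / arb. u.)",
                  y = if (normalized) "normalized PSD" else "PSD") +
    ggplot2::theme_minimal()
}

#' @export
plot.binding_spectrum <- function(x, ...) print(autoplot(x, ...))

#' Plot mean spectral entropy versus binding strength
#'
#' Open circles with standard-deviation error bars, one point per binding
#' strength.
#'
#' @param object A `binding_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binding_sweep <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$omega, y = .data$mean_entropy)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_entropy - .data$sd_entropy,
                                        ymax = .data$mean_entropy + .data$sd_entropy),
                           width = 0.02) +
    ggplot2::geom_point(shape = 1, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = expression(paste("binding strength ", omega)),
                  y = "spectral entropy H") +
    ggplot2::theme_minimal()
}

#' @export
plot.binding_sweep <- function(x, ...) print(autoplot(x, ...))
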