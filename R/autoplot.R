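# ggplot2 autoplot methods.

#' Plot a complex field as amplitude and phase panels
#'
#' @param object A `complex_field`.
#' @param ... Unused.
#' @return A ggplot (faceted raster).
#' @method autoplot complex_field
#' @export
autoplot.complex_field <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(df, c("amplitude", "phase"),
                              names_to = "channel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = NULL)
}

#' Plot a detector trace
#'
#' @param object A `detector_trace`.
#' @param max_samples Decimation cap (default 5000 points plotted).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detector_trace
#' @export
autoplot.detector_trace <- function(object, max_samples = 5000, ...) {
  ggplot2::ggplot(tidy(object, max_samples = max_samples),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "detector signal")
}

#' Plot a spectrum's modulus
#'
#' @param object A `spectrum`.
#' @param log10 Plot log10 modulus (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum
#' @export
autoplot.spectrum <- function(object, log10 = TRUE, ...) {
  df <- tidy(object)
  if (log10) df$modulus <- base::log10(df$modulus + .Machine$double.xmin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency / 1e6,
                                   y = .data$modulus)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency (MHz)",
                  y = if (log10) "log10 |E(f)|" else "|E(f)|")
}

#' Plot the beat-frequency plan of a spectral map
#'
#' @param object A `spectral_map`.
#' @param ... Unused.
#' @return A ggplot raster of |beat| over the pixel grid.
#' @method autoplot spectral_map
#' @export
autoplot.spectral_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$m,
                                   fill = abs(.data$beat) / 1e6)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "n (x pixel)", y = "m (y pixel)", fill = "|beat| (MHz)")
}
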