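# broom-style tidiers for the package's result objects.

#' Tidy a complex field into a long tibble
#'
#' @param x A `complex_field`.
#' @param ... Unused.
#' @return Tibble with `x`, `y` (pixel indices), `amplitude`, `phase`.
#' @method tidy complex_field
#' @export
tidy.complex_field <- function(x, ...) {
  nx <- nrow(x); ny <- ncol(x)
  amp <- as.vector(field_amplitude(x))
  ph <- as.vector(field_phase(x))
  tibble::tibble(
    x = rep(seq_len(nx), ny),
    y = rep(seq_len(ny), each = nx),
    amplitude = amp,
    phase = ph
  )
}

#' Tidy a detector trace into a time/value tibble
#'
#' @param x A `detector_trace`.
#' @param max_samples Cap on returned rows (evenly decimated); `Inf` keeps
#'   all samples.
#' @param ... Unused.
#' @return Tibble with `time` (s) and `value`.
#' @method tidy detector_trace
#' @export
tidy.detector_trace <- function(x, max_samples = Inf, ...) {
  n <- length(x)
  idx <- if (n > max_samples) {
    unique(round(seq(1, n, length.out = max_samples)))
  } else {
    seq_len(n)
  }
  fs <- attr(x, "sampling_rate")
  tibble::tibble(time = attr(x, "start_time") + (idx - 1) / fs,
                 value = as.numeric(x)[idx])
}

#' Tidy a spectrum into a frequency-domain tibble
#'
#' @param x A `spectrum`.
#' @param ... Unused.
#' @return Tibble with `frequency` (Hz), `modulus`, `re`, `im`.
#' @method tidy spectrum
#' @export
tidy.spectrum <- function(x, ...) {
  tibble::tibble(
    frequency = (seq_len(x$n_bins) - 1) * x$bin_width,
    modulus = Mod(x$values),
    re = Re(x$values),
    im = Im(x$values)
  )
}

#' Tidy a design report's collision list
#'
#' @param x A `design_report`.
#' @param ... Unused.
#' @return The collisions tibble (zero rows for a passing design).
#' @method tidy design_report
#' @export
tidy.design_report <- function(x, ...) x$collisions

#' One-row summary of a design report
#'
#' @param x A `design_report`.
#' @param ... Unused.
#' @return One-row tibble: `passed`, `n_pixels`, `n_collisions`,
#'   `dc_margin`, `nyquist_margin`, `residual_1d_separation`.
#' @method glance design_report
#' @export
glance.design_report <- function(x, ...) {
  tibble::tibble(
    passed = x$passed, n_pixels = x$n_pixels,
    n_collisions = nrow(x$collisions), dc_margin = x$dc_margin,
    nyquist_margin = x$nyquist_margin,
    residual_1d_separation = x$residual_1d_separation
  )
}

#' One-row summary of a spectral map
#'
#' @param x A `spectral_map`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, beat range, conjugate-pixel count.
#' @method glance spectral_map
#' @export
glance.spectral_map <- function(x, ...) {
  tibble::tibble(
    nx = attr(x, "nx"), ny = attr(x, "ny"), n_pixels = nrow(x),
    f0 = attr(x, "f0"), bin_width = attr(x, "bin_width"),
    min_abs_beat = min(abs(x$beat)), max_abs_beat = max(abs(x$beat)),
    n_conjugate = sum(x$conjugate)
  )
}
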