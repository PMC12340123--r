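# FFT demodulation: spectrum, per-pixel bin extraction, null calibration,
# frame streaming.

#' One-sided FFT spectrum of a detector trace
#'
#' Normalization is `values = FFT / length`, so a pure cosine of amplitude C
#' on an exact bin reads |value| = C/2 there (rectangular window).  The Hann
#' window (periodic, amplitude-corrected by its coherent gain of 0.5) is
#' offered for traces whose tones are not grid-locked.
#'
#' @param trace A `detector_trace` of length >= 2.
#' @param window `"rect"` or `"hann"`.
#' @return A `spectrum`: list with complex `values` (bins 0 .. Nyquist),
#'   `bin_width` (Hz), `n_bins`, `window`, `sampling_rate`.
#' @export
fft_spectrum <- function(trace, window = c("rect", "hann")) {
  window <- match.arg(window)
  stopifnot(inherits(trace, "detector_trace"))
  x <- as.numeric(trace)
  N <- length(x)
  if (N < 2) stop("trace length must be >= 2", call. = FALSE)
  fs <- attr(trace, "sampling_rate")
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1) / N)
    x <- x * w / mean(w)  # coherent-gain correction
  }
  full <- fft(x) / N
  n_bins <- floor(N / 2) + 1L
  structure(
    list(values = full[seq_len(n_bins)], bin_width = fs / N,
         n_bins = n_bins, window = window, sampling_rate = fs),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bins of %.6g kHz (%s window), up to %.6g MHz\n",
              x$n_bins, x$bin_width / 1e3, x$window,
              (x$n_bins - 1) * x$bin_width / 1e6))
  invisible(x)
}

#' Extract the complex object from a spectrum
#'
#' Reads, for every pixel, the complex bin at `|beat| / bin_width`;
#' conjugates pixels whose beat is negative (their information sits in the
#' mirror term of the two-sided spectrum); divides by the calibration
#' factors when a table is given.  Without calibration the result is
#' proportional to `E_S * E_R * O`.
#'
#' @param spectrum A [fft_spectrum()] result.
#' @param map A `spectral_map`; every |beat| must land on an exact bin, or
#'   within half a bin (nearest-bin lookup, reported via `message()`).
#' @param calib Optional `calibration_table` from [null_calibrate()].
#' @return A `complex_field`.
#' @export
extract_field <- function(spectrum, map, calib = NULL) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(map, "spectral_map"))
  k_exact <- abs(map$beat) / spectrum$bin_width
  k <- round(k_exact)
  dev <- max(abs(k_exact - k))
  if (dev > 0.5 + 1e-9) {
    stop("a |beat| falls more than half a bin from the FFT grid", call. = FALSE)
  }
  if (dev > 1e-6) {
    message(sprintf("nearest-bin lookup: worst off-grid deviation %.3g bins", dev))
  }
  if (any(k >= spectrum$n_bins)) {
    stop("beat frequency beyond the spectrum's Nyquist bin", call. = FALSE)
  }
  vals <- spectrum$values[k + 1L]
  vals[map$conjugate] <- Conj(vals[map$conjugate])
  nx <- attr(map, "nx"); ny <- attr(map, "ny")
  if (!is.null(calib)) {
    stopifnot(inherits(calib, "calibration_table"))
    f <- unclass(calib)
    if (!all(dim(f) == c(nx, ny))) {
      stop("calibration table dimensions do not match the map", call. = FALSE)
    }
    if (any(!is.finite(f)) || any(Mod(f) == 0)) {
      stop("calibration table has missing or zero entries", call. = FALSE)
    }
    vals <- vals / as.vector(f)
  }
  as_complex_field(matrix(vals, nx, ny))
}

#' Build a null-calibration table from a flat-field acquisition
#'
#' The raw extracted complex values of a unit-amplitude, zero-phase scene
#' capture every per-pixel system factor (tone amplitude, phase, path
#' length, `E_S * E_R`).  Dividing later extractions by these factors maps
#' the flat scene to exactly 1 everywhere and removes the system response
#' from any other scene.
#'
#' @param flat_trace `detector_trace` acquired with the flat (null) scene.
#' @param map The `spectral_map` used for the acquisition.
#' @param window Passed to [fft_spectrum()].
#' @param eps Dead-pixel threshold: any factor with modulus below
#'   `eps * max(modulus)` is an error naming the pixels.
#' @param source Identifier string stored with the table.
#' @return A `calibration_table` (complex nx x ny matrix with a `source`
#'   attribute).
#' @export
null_calibrate <- function(flat_trace, map, window = "rect", eps = 1e-6,
                           source = "null") {
  raw <- extract_field(fft_spectrum(flat_trace, window), map)
  f <- unclass(raw)
  mods <- Mod(f)
  dead <- which(mods < eps * max(mods), arr.ind = TRUE)
  if (nrow(dead) > 0) {
    stop(sprintf("null calibration found %d dead pixel(s): %s", nrow(dead),
                 paste(sprintf("(%d,%d)", dead[, 1], dead[, 2]),
                       collapse = " ")),
         call. = FALSE)
  }
  structure(f, class = c("calibration_table", "matrix", "array"),
            source = source)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d x %d px from '%s', |factor| in [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "source"), min(Mod(x)), max(Mod(x))))
  invisible(x)
}

#' Reconstruct one frame from a trace
#'
#' Convenience wrapper: [fft_spectrum()] then [extract_field()].
#'
#' @inheritParams extract_field
#' @param trace A single-frame `detector_trace`.
#' @param window Passed to [fft_spectrum()].
#' @return A `complex_field`.
#' @export
reconstruct_frame <- function(trace, map, calib = NULL, window = "rect") {
  extract_field(fft_spectrum(trace, window), map, calib)
}

#' Stream a long trace into per-frame reconstructions
#'
#' Partitions the trace into consecutive non-overlapping frames of
#' `frame_duration`, reconstructs each independently, and returns the fields
#' with timestamps.  A trailing partial frame is discarded with a warning
#' reporting the dropped sample count.
#'
#' @param long_trace A `detector_trace` at least one frame long.
#' @param map The `spectral_map`.
#' @param calib Optional `calibration_table`.
#' @param frame_duration Frame duration in s.
#' @param window Passed to [fft_spectrum()].
#' @return A `scene_sequence` of reconstructed fields; its metadata records
#'   the dropped-sample count.
#' @export
stream_frames <- function(long_trace, map, calib = NULL, frame_duration,
                          window = "rect") {
  stopifnot(inherits(long_trace, "detector_trace"), frame_duration > 0)
  fs <- attr(long_trace, "sampling_rate")
  n_samp <- round(fs * frame_duration)
  n_total <- length(long_trace)
  n_frames <- n_total %/% n_samp
  if (n_frames < 1) stop("trace shorter than one frame", call. = FALSE)
  dropped <- n_total - n_frames * n_samp
  if (dropped > 0) {
    warning(sprintf("discarding trailing partial frame (%d samples)", dropped),
            call. = FALSE)
  }
  x <- as.numeric(long_trace)
  t0 <- attr(long_trace, "start_time")
  frames <- lapply(seq_len(n_frames), function(i) {
    seg <- detector_trace(x[((i - 1) * n_samp + 1):(i * n_samp)],
                          sampling_rate = fs,
                          start_time = t0 + (i - 1) * frame_duration)
    reconstruct_frame(seg, map, calib, window)
  })
  scene_sequence(frames,
                 timestamps = t0 + (seq_len(n_frames) - 1) * frame_duration,
                 metadata = list(generator = "stream_frames",
                                 dropped_samples = dropped,
                                 frame_duration = frame_duration,
                                 window = window))
}
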