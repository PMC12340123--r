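# Tone-comb construction and pixel -> beat-frequency mapping.

#' Build a one-axis frequency comb
#'
#' Places comb teeth at `band_start + offset + k * spacing` for
#' `k = 0, 1, ...` as long as the tooth stays at or below `band_end`.  With
#' `grid > 0` the comb is *grid-locked*: `band_start`, `spacing` and `offset`
#' must all be integer multiples of `grid`, so every tooth falls on an exact
#' analysis bin (leakage-free rectangular-window extraction).
#'
#' @param band_start,band_end Comb band limits in Hz (`band_end >=
#'   band_start`).
#' @param spacing Nominal tooth spacing in Hz (> 0).
#' @param offset Sub-spacing shift applied to the whole comb, Hz.
#' @param grid Analysis grid in Hz; `0` disables grid-locking.
#' @param axis `"x"` or `"y"`; which deflector the comb drives.
#' @param device_band Length-2 numeric, the deflector's allowed band in Hz.
#'   Tones outside it are an error.
#' @return A `freq_comb` object: list with `axis`, `tones` (Hz, strictly
#'   increasing), `band_low`, `band_high`, `spacing`, `offset`, `grid`.
#' @examples
#' comb <- build_comb(63e6, 88e6, spacing = 25e6 / 79)
#' length(comb$tones)  # 80
#' @export
build_comb <- function(band_start, band_end, spacing, offset = 0, grid = 0,
                       axis = c("x", "y"), device_band = c(61e6, 91e6)) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(band_start), is.numeric(band_end), is.numeric(spacing),
            length(band_start) == 1, length(band_end) == 1)
  if (band_end < band_start) {
    stop("`band_end` must be >= `band_start`", call. = FALSE)
  }
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  if (offset < 0) stop("`offset` must be >= 0", call. = FALSE)
  if (grid < 0) stop("`grid` must be >= 0", call. = FALSE)
  if (grid > 0) {
    for (nm in c("band_start", "spacing", "offset")) {
      v <- get(nm)
      if (abs(v / grid - round(v / grid)) > 1e-9) {
        stop(sprintf("grid-locking: `%s` (%g Hz) is not an integer multiple of grid (%g Hz)",
                     nm, v, grid), call. = FALSE)
      }
    }
  }
  span <- band_end - band_start - offset
  if (span < -1e-9 * max(1, abs(band_end))) {
    stop("empty comb: no tone fits in [band_start, band_end] with this offset",
         call. = FALSE)
  }
  n_tones <- floor(span / spacing + 1e-9) + 1
  tones <- band_start + offset + (seq_len(n_tones) - 1) * spacing
  if (grid > 0) tones <- round(tones / grid) * grid
  if (any(tones < device_band[1] - 1e-9) || any(tones > device_band[2] + 1e-9)) {
    stop(sprintf("comb tone outside device band [%g, %g] Hz",
                 device_band[1], device_band[2]), call. = FALSE)
  }
  structure(
    list(axis = axis, tones = tones, band_low = band_start,
         band_high = band_end, spacing = spacing, offset = offset,
         grid = grid, device_band = device_band),
    class = "freq_comb"
  )
}

#' @export
print.freq_comb <- function(x, ...) {
  cat(sprintf("<freq_comb %s> %d tones, %.6g - %.6g MHz, spacing %.6g kHz, offset %.6g kHz%s\n",
              x$axis, length(x$tones), min(x$tones) / 1e6, max(x$tones) / 1e6,
              x$spacing / 1e3, x$offset / 1e3,
              if (x$grid > 0) sprintf(", grid %.6g kHz", x$grid / 1e3) else ""))
  invisible(x)
}

#' Map every pixel to its heterodyne beat frequency
#'
#' For pixel `(n, m)` the encoded optical frequency is
#' `f0 - f_x(n) + f_y(m)`, so its beat against the unmodulated carrier is
#' `beat(n, m) = f_y(m) - f_x(n)`.  Pixels with a negative beat carry their
#' information in the conjugate (mirror) spectral bin and are flagged for
#' conjugation at extraction.  No uniqueness check is performed here; see
#' [verify_unique_mapping()].
#'
#' @param comb_x,comb_y [build_comb()] results for the two deflector axes.
#' @param f0 Base (carrier) frequency in Hz; stored for bookkeeping only —
#'   all beats are carrier-relative.
#' @param bin_width Analysis bin width in Hz (1 / frame duration); used by
#'   the verifier and at extraction.
#' @return A `spectral_map`: a tibble with one row per pixel and columns
#'   `n`, `m` (1-based pixel indices), `f_x`, `f_y` (tone frequencies, Hz),
#'   `beat` (signed, Hz) and `conjugate` (logical).  Attributes: `nx`, `ny`,
#'   `f0`, `bin_width`, `comb_x`, `comb_y`.  Row order is `n` fastest
#'   (column-major, matching matrix storage of fields).
#' @examples
#' map <- build_spectral_map(build_comb(63e6, 63e6, 1e3),
#'                           build_comb(88e6, 88e6, 1e3, axis = "y"))
#' map$beat  # 25 MHz
#' @export
build_spectral_map <- function(comb_x, comb_y, f0 = 0, bin_width = 1e3) {
  stopifnot(inherits(comb_x, "freq_comb"), inherits(comb_y, "freq_comb"))
  if (length(comb_x$tones) < 1 || length(comb_y$tones) < 1) {
    stop("both combs must be nonempty", call. = FALSE)
  }
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  nx <- length(comb_x$tones)
  ny <- length(comb_y$tones)
  grid <- tidyr::expand_grid(m = seq_len(ny), n = seq_len(nx))
  out <- tibble::tibble(
    n = grid$n,
    m = grid$m,
    f_x = comb_x$tones[grid$n],
    f_y = comb_y$tones[grid$m]
  )
  out$beat <- out$f_y - out$f_x
  out$conjugate <- out$beat < 0
  attr(out, "nx") <- nx
  attr(out, "ny") <- ny
  attr(out, "f0") <- f0
  attr(out, "bin_width") <- bin_width
  attr(out, "comb_x") <- comb_x
  attr(out, "comb_y") <- comb_y
  class(out) <- c("spectral_map", class(out))
  out
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> %d x %d pixels, |beat| in [%.6g, %.6g] kHz, bin %.6g kHz\n",
              attr(x, "nx"), attr(x, "ny"),
              min(abs(x$beat)) / 1e3, max(abs(x$beat)) / 1e3,
              attr(x, "bin_width") / 1e3))
  NextMethod()
}

#' Exhaustively verify a spectral map is collision-free
#'
#' A usable encoding needs four properties, all checked here:
#' \enumerate{
#'   \item all |beat| values pairwise distinct by at least `bin_width`
#'     (this also covers the mirror condition `beat_i = -beat_j`, since both
#'     signs fold onto |beat| in the real detector spectrum);
#'   \item `min |beat| >= dc_guard` — separation from the DC synthesis term;
#'   \item `max |beat| < acq_nyquist`;
#'   \item every |beat| at least `bin_width` away from every residual
#'     1D-diffraction beat `|f_x(n) - f_x(n')|`.
#' }
#' Failures are reported, never raised: a failing design comes back with
#' `passed = FALSE` and the offending pixel pairs listed.
#'
#' @param map A [build_spectral_map()] result.
#' @param acq_nyquist Acquisition Nyquist frequency in Hz (sampling rate / 2).
#' @param dc_guard Minimum allowed |beat| in Hz.
#' @return A `design_report`: list with `passed`, `collisions` (tibble of
#'   offending pixel pairs), `dc_margin`, `nyquist_margin`,
#'   `residual_1d_separation`, plus the thresholds used.
#' @export
verify_unique_mapping <- function(map, acq_nyquist, dc_guard = 50e3) {
  stopifnot(inherits(map, "spectral_map"))
  bin_width <- attr(map, "bin_width")
  tol <- bin_width * (1 - 1e-9)
  ab <- abs(map$beat)
  ord <- order(ab)
  abs_sorted <- ab[ord]

  # pairwise distinctness: after sorting, only adjacent pairs can violate
  gaps <- diff(abs_sorted)
  bad <- which(gaps < tol)
  collisions <- tibble::tibble(
    n1 = map$n[ord[bad]], m1 = map$m[ord[bad]], beat1 = map$beat[ord[bad]],
    n2 = map$n[ord[bad + 1]], m2 = map$m[ord[bad + 1]],
    beat2 = map$beat[ord[bad + 1]]
  )

  dc_margin <- abs_sorted[1]
  nyquist_margin <- acq_nyquist - abs_sorted[length(abs_sorted)]

  comb_x <- attr(map, "comb_x")
  fx <- comb_x$tones
  if (length(fx) > 1) {
    d1 <- sort(unique(abs(as.vector(outer(fx, fx, "-")))))
    d1 <- d1[d1 > 0]
    res_sep <- min_set_distance(abs_sorted, d1)
  } else {
    res_sep <- Inf
  }

  passed <- nrow(collisions) == 0 &&
    dc_margin >= dc_guard &&
    nyquist_margin > 0 &&
    res_sep >= tol
  structure(
    list(passed = passed, collisions = collisions, dc_margin = dc_margin,
         nyquist_margin = nyquist_margin, residual_1d_separation = res_sep,
         dc_guard = dc_guard, bin_width = bin_width,
         acq_nyquist = acq_nyquist, n_pixels = nrow(map)),
    class = "design_report"
  )
}

# minimum |a_i - b_j| between a sorted vector a and a sorted vector b
min_set_distance <- function(a, b) {
  i <- findInterval(a, b)
  lo <- ifelse(i >= 1, a - b[pmax(i, 1)], Inf)
  hi <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - a, Inf)
  min(pmin(abs(lo), abs(hi)))
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s\n", if (x$passed) "PASSED" else "FAILED"))
  cat(sprintf("  pixels: %d | collisions: %d | DC margin: %.6g kHz (guard %.6g)\n",
              x$n_pixels, nrow(x$collisions), x$dc_margin / 1e3,
              x$dc_guard / 1e3))
  cat(sprintf("  Nyquist margin: %.6g kHz | 1D-beat separation: %.6g kHz | bin: %.6g kHz\n",
              x$nyquist_margin / 1e3, x$residual_1d_separation / 1e3,
              x$bin_width / 1e3))
  if (nrow(x$collisions) > 0) {
    cat("  first collisions:\n")
    print(utils::head(x$collisions, 5))
  }
  invisible(x)
}

#' Default 80 x 81 comb design
#'
#' The packaged default encoding: `comb_x` = 63 MHz + k * 307 kHz
#' (k = 0..79, 80 tones, top tone 87.253 MHz) and `comb_y` = 63 MHz + 77 kHz
#' + k * 309 kHz (k = 0..80, 81 tones, top tone 87.797 MHz), all on a 1 kHz
#' grid so that 1 ms frames at 50 MSa/s are leakage-free.  The coprime
#' spacings (307 is prime) and the 77 kHz shift make all 6480 |beat| values
#' distinct, keep the smallest |beat| (74 kHz) clear of DC, keep the largest
#' (24.797 MHz) under the 25 MHz acquisition Nyquist, and keep every |beat|
#' at least 70 kHz away from any residual 1D-diffraction beat.  The design is
#' validated, not trusted: the returned list carries the
#' [verify_unique_mapping()] report and this function errors if verification
#' ever fails.
#'
#' @param f0 Carrier frequency bookkeeping value, Hz.
#' @param frame_duration Analysis frame duration in s; sets the grid / bin
#'   width to `1 / frame_duration`.
#' @param sampling_rate Acquisition rate in Sa/s (sets the Nyquist used for
#'   verification).
#' @param dc_guard DC guard band in Hz.
#' @return List with `comb_x`, `comb_y`, `map` and `report`.
#' @export
default_design <- function(f0 = 0, frame_duration = 1e-3,
                           sampling_rate = 50e6, dc_guard = 50e3) {
  grid <- 1 / frame_duration
  comb_x <- build_comb(63e6, 63e6 + 79 * 307e3, spacing = 307e3, offset = 0,
                       grid = grid, axis = "x")
  comb_y <- build_comb(63e6, 63e6 + 77e3 + 80 * 309e3, spacing = 309e3,
                       offset = 77e3, grid = grid, axis = "y")
  map <- build_spectral_map(comb_x, comb_y, f0 = f0, bin_width = grid)
  report <- verify_unique_mapping(map, acq_nyquist = sampling_rate / 2,
                                  dc_guard = dc_guard)
  if (!report$passed) {
    stop("internal error: default design failed verification", call. = FALSE)
  }
  list(comb_x = comb_x, comb_y = comb_y, map = map, report = report)
}
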