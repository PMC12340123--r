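# Figures of merit: CNR, SBP-T, USAF line widths, dip profiles, deflector
# optics (pixel pitch, field of view, time-bandwidth product).

#' Contrast-to-noise ratio of an amplitude image
#'
#' `(mean over target - mean over background) / sd over background`; the
#' sign is preserved.
#'
#' @param image Numeric matrix, or a `complex_field` (its amplitude is
#'   used).
#' @param target_mask,background_mask Logical matrices of the image's
#'   dimensions; disjoint, each with at least 2 pixels.
#' @return CNR (numeric scalar).
#' @examples
#' img <- matrix(2, 10, 10); img[4:6, 4:6] <- 10
#' bg <- img == 2; bg[1] <- FALSE
#' img[1, 1] <- 3  # some background fluctuation
#' cnr(img, img == 10, bg)
#' @export
cnr <- function(image, target_mask, background_mask) {
  if (inherits(image, "complex_field")) image <- field_amplitude(image)
  stopifnot(is.matrix(image), is.logical(target_mask),
            is.logical(background_mask),
            all(dim(target_mask) == dim(image)),
            all(dim(background_mask) == dim(image)))
  if (any(target_mask & background_mask)) {
    stop("target and background masks overlap", call. = FALSE)
  }
  if (sum(target_mask) < 2 || sum(background_mask) < 2) {
    stop("each mask needs at least 2 pixels", call. = FALSE)
  }
  s <- sd(image[background_mask])
  if (s == 0) stop("background has zero fluctuation; CNR undefined", call. = FALSE)
  (mean(image[target_mask]) - mean(image[background_mask])) / s
}

#' Space-bandwidth-time product
#'
#' Information throughput: frames per second times frame size, optionally
#' times the number of information channels (2 for complex-field systems
#' reporting amplitude and phase, 1 for intensity-only).
#'
#' @param fps Frame rate, Hz.
#' @param nx,ny Frame size in pixels.
#' @param channels 1 or 2.
#' @return SBP-T in pixels/s (exact product).
#' @seealso [sbpt_printed()] for the 2-significant-figure form used when
#'   quoting headline values.
#' @examples
#' sbpt(1000, 80, 81, channels = 2)  # 12,960,000
#' @export
sbpt <- function(fps, nx, ny, channels = 1) {
  stopifnot(fps > 0, nx > 0, ny > 0, channels %in% c(1, 2))
  fps * nx * ny * channels
}

#' @rdname sbpt
#' @export
sbpt_printed <- function(fps, nx, ny, channels = 1) {
  signif(sbpt(fps, nx, ny, channels), 2)
}

#' USAF-1951 bar width
#'
#' Group `g`, element `e` of the USAF-1951 chart has resolution
#' `R = 2^(g + (e - 1)/6)` line pairs per mm; one bar (line) is
#' `1000 / (2 R)` micrometres wide.
#'
#' @param group Integer group number.
#' @param element Element 1..6.
#' @return Line width in micrometres.
#' @examples
#' usaf_linewidth(7, 1)  # 3.91 um
#' @export
usaf_linewidth <- function(group, element) {
  stopifnot(element %in% 1:6)
  R <- 2^(group + (element - 1) / 6)  # lp/mm
  1000 / (2 * R)
}

#' Locate dips in a 1D profile
#'
#' Finds local minima (plateaus allowed) whose prominence — depth below the
#' lower of the two enclosing barriers, as in standard peak-finding — is at
#' least `prominence`.  Used to verify a three-bar element is resolved
#' (exactly 3 dips across the bar region).
#'
#' @param profile Numeric vector, length >= 3.
#' @param prominence Minimum prominence; default 10% of the profile's
#'   dynamic range.
#' @return Tibble with `position` (index, plateau centres), `value` and
#'   `prominence`, sorted by position.
#' @export
profile_dips <- function(profile, prominence = NULL) {
  stopifnot(is.numeric(profile), length(profile) >= 3)
  if (is.null(prominence)) prominence <- 0.1 * diff(range(profile))
  r <- rle(profile)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nruns <- length(v)
  pos <- integer(0); val <- numeric(0); prom <- numeric(0)
  if (nruns >= 3) {
    for (i in 2:(nruns - 1)) {
      if (v[i] < v[i - 1] && v[i] < v[i + 1]) {
        # barrier on each side: highest value between the dip and the
        # nearest strictly lower point (or the profile edge)
        left <- v[seq_len(i - 1)]
        lower <- which(left < v[i])
        lstart <- if (length(lower)) max(lower) + 1L else 1L
        lb <- max(left[lstart:(i - 1)])
        right <- v[(i + 1):nruns]
        lower_r <- which(right < v[i])
        rend <- if (length(lower_r)) min(lower_r) - 1L else length(right)
        rb <- max(right[seq_len(rend)])
        p <- min(lb, rb) - v[i]
        if (p >= prominence) {
          pos <- c(pos, as.integer(round((starts[i] + ends[i]) / 2)))
          val <- c(val, v[i])
          prom <- c(prom, p)
        }
      }
    }
  }
  tibble::tibble(position = pos, value = val, prominence = prom)
}

#' Deflector optics configuration
#'
#' @param wavelength Optical wavelength, m.
#' @param objective_focal Objective focal length, m.
#' @param acoustic_velocity Acoustic velocity in the deflector crystal, m/s.
#'   The 650 m/s default is the slow-shear TeO2 value typical of this
#'   deflector class — an assumption, configurable, and reported as such.
#' @param beam_diameter Beam diameter at the deflector aperture, m.
#' @param comb_span Modulation bandwidth (comb span) in Hz.
#' @param tones_per_axis Number of comb tones on the axis.
#' @return An `optics_config` list.
#' @export
optics_config <- function(wavelength = 1030e-9, objective_focal = 7.5e-3,
                          acoustic_velocity = 650, beam_diameter = 5e-3,
                          comb_span = 25e6, tones_per_axis = 80) {
  stopifnot(wavelength > 0, objective_focal > 0, acoustic_velocity > 0,
            beam_diameter > 0, comb_span >= 0, tones_per_axis >= 1)
  structure(
    list(wavelength = wavelength, objective_focal = objective_focal,
         acoustic_velocity = acoustic_velocity,
         beam_diameter = beam_diameter, comb_span = comb_span,
         tones_per_axis = as.integer(tones_per_axis)),
    class = "optics_config"
  )
}

#' Acousto-optic pixel pitch and field of view
#'
#' The deflection angle of an acousto-optic deflector is proportional to
#' its drive frequency, `theta = lambda f / V`; one comb-tooth step of
#' `comb_span / (tones - 1)` therefore advances the beam by
#' `dtheta = lambda * (comb_span / (tones - 1)) / V`, which the objective
#' turns into a focal-plane pitch `f_obj * dtheta`.  The field of view is
#' `(tones - 1)` pitches.
#'
#' @param optics An [optics_config()] with `tones_per_axis >= 2`.
#' @return One-row tibble with `pitch` and `fov` in metres.
#' @examples
#' pixel_pitch_and_fov(optics_config())  # pitch 3.76 um, fov 297 um
#' @export
pixel_pitch_and_fov <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  if (optics$tones_per_axis < 2) {
    stop("`tones_per_axis` must be >= 2 for a pitch to exist", call. = FALSE)
  }
  dtheta <- optics$wavelength *
    (optics$comb_span / (optics$tones_per_axis - 1)) /
    optics$acoustic_velocity
  pitch <- optics$objective_focal * dtheta
  tibble::tibble(pitch = pitch, fov = (optics$tones_per_axis - 1) * pitch)
}

#' Time-bandwidth product of a deflector
#'
#' Acoustic transit time across the beam aperture times the modulation
#' bandwidth, `N = (D / V) * comb_span`: the number of resolvable
#' deflection spots per axis.
#'
#' @param optics An [optics_config()].
#' @return N (numeric scalar).
#' @export
time_bandwidth_product <- function(optics) {
  stopifnot(inherits(optics, "optics_config"))
  optics$beam_diameter / optics$acoustic_velocity * optics$comb_span
}

#' Illumination intensity over the field of view
#'
#' @param power_w Total optical power on the sample, W.
#' @param fov_m Side length of the (square) illuminated area, m.
#' @return Intensity in mW/cm^2.
#' @examples
#' illumination_intensity(100e-6, 300e-6)  # ~111 mW/cm^2
#' @export
illumination_intensity <- function(power_w, fov_m) {
  stopifnot(power_w >= 0, fov_m > 0)
  power_w / fov_m^2 * 0.1  # W/m^2 -> mW/cm^2
}

#' Raw-data storage estimate
#'
#' @param duration_s Recording duration, s.
#' @param sampling_rate Sa/s.
#' @param bytes_per_sample Bytes per stored sample.
#' @return Storage in decimal gigabytes (1e9 bytes).
#' @examples
#' storage_estimate(60, 50e6)  # 3 GB
#' @export
storage_estimate <- function(duration_s, sampling_rate, bytes_per_sample = 1) {
  stopifnot(duration_s >= 0, sampling_rate > 0, bytes_per_sample > 0)
  duration_s * sampling_rate * bytes_per_sample / 1e9
}
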