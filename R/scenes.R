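# Synthetic complex-field scenes: resolution bar targets, transparent phase
# droplets, mixing gradients, and dynamic sequences.

#' Three-bar resolution target
#'
#' A USAF-style element: three parallel bars with width equal to the gap and
#' length five times the width, centered in the frame.  Background amplitude
#' is 1, bar amplitude `1 - contrast`, phase 0.  With `orientation =
#' "horizontal"` the bars are stacked along x (rows), so a profile along x
#' through the element crosses all three bars; `"vertical"` is the
#' transposed layout.
#'
#' @param nx,ny Frame size in pixels.
#' @param bar_width_px Bar (and gap) width in pixels, >= 1.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param contrast Bar depth in `[0, 1]`; 0 gives a uniform field.
#' @return A `complex_field`.
#' @export
bar_target <- function(nx, ny, bar_width_px, orientation = c("horizontal", "vertical"),
                       contrast = 1) {
  orientation <- match.arg(orientation)
  w <- as.integer(bar_width_px)
  if (w < 1) stop("`bar_width_px` must be >= 1", call. = FALSE)
  if (contrast < 0 || contrast > 1) stop("`contrast` must be in [0, 1]", call. = FALSE)
  ext <- 5L * w  # element extent: 3 bars + 2 gaps across, length 5w along
  if (orientation == "horizontal") {
    if (ext > nx || ext > ny) stop("bar pattern larger than frame", call. = FALSE)
    amp <- matrix(1, nx, ny)
    r0 <- (nx - ext) %/% 2L
    c0 <- (ny - ext) %/% 2L
    for (b in 0:2) {
      rows <- (r0 + 2L * b * w + 1L):(r0 + (2L * b + 1L) * w)
      amp[rows, (c0 + 1L):(c0 + ext)] <- 1 - contrast
    }
    complex_field(amp, 0)
  } else {
    tgt <- bar_target(ny, nx, w, "horizontal", contrast)
    as_complex_field(t(unclass(tgt)))
  }
}

#' Transparent phase-droplet scene
#'
#' Pure-phase scene (amplitude identically 1) emulating transparent droplets
#' with an index contrast: each droplet adds a spherical-cap phase profile
#' `peak_phase * sqrt(max(0, 1 - r^2 / R^2))`.  Overlapping droplets sum,
#' then the total phase is wrapped.
#'
#' @param nx,ny Frame size in pixels.
#' @param droplets List of droplets, each a list/vector with elements
#'   `center` (length-2, pixel coordinates `(x, y)`), `radius` (px, >= 1)
#'   and `peak_phase` (radians).
#' @return A `complex_field` with unit amplitude.
#' @export
phase_droplet_scene <- function(nx, ny, droplets = list()) {
  phase <- matrix(0, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  for (d in droplets) {
    if (d$radius < 1) stop("droplet radius must be >= 1 px", call. = FALSE)
    r2 <- ((xs - d$center[1])^2 + (ys - d$center[2])^2) / d$radius^2
    phase <- phase + d$peak_phase * sqrt(pmax(0, 1 - r2))
  }
  complex_field(matrix(1, nx, ny), phase)
}

#' Lateral mixing-gradient phase scene
#'
#' Two transparent solutions meeting at a boundary along x: the phase steps
#' by `phase_step` across an error-function profile of 1/e half-width
#' `width` (pixels), emulating a diffusing interface.  Droplets may be
#' superimposed.  Amplitude is identically 1.
#'
#' @param nx,ny Frame size in pixels.
#' @param boundary_x Boundary position along x (pixels).
#' @param width Interface width in pixels (> 0).
#' @param phase_step Total phase difference across the boundary, radians.
#' @param droplets Optional droplet list as in [phase_droplet_scene()].
#' @return A `complex_field` with unit amplitude.
#' @export
mixing_gradient_scene <- function(nx, ny, boundary_x = (nx + 1) / 2,
                                  width = 4, phase_step = pi / 2,
                                  droplets = list()) {
  stopifnot(width > 0)
  base <- phase_droplet_scene(nx, ny, droplets)
  ramp <- phase_step / 2 * (1 + pracma::erf((seq_len(nx) - boundary_x) / width))
  phase <- field_phase(base) + matrix(ramp, nx, ny)
  complex_field(matrix(1, nx, ny), phase)
}

#' Dynamic scene sequence by periodic translation
#'
#' Generates a base field and translates it by `velocity_px_per_frame`
#' pixels per frame with periodic wrap, producing one field per frame at
#' `frame_duration` intervals.
#'
#' @param base_generator Either a `complex_field` or a function; a function
#'   is called as `base_generator(seed)` to produce the frame-0 field.
#' @param velocity_px_per_frame Length-2 numeric `(vx, vy)` in px/frame.
#' @param n_frames Number of frames, >= 1.
#' @param frame_duration Frame period in s.
#' @param seed Integer seed forwarded to `base_generator`.
#' @return A `scene_sequence`: list with `frames` (list of `complex_field`),
#'   `timestamps` (s, strictly increasing) and `metadata`.
#' @export
dynamic_sequence <- function(base_generator, velocity_px_per_frame = c(0, 0),
                             n_frames = 1, frame_duration = 1e-3, seed = 1) {
  stopifnot(n_frames >= 1, frame_duration > 0)
  v <- rep_len(as.numeric(velocity_px_per_frame), 2)
  base <- if (is.function(base_generator)) base_generator(seed) else base_generator
  stopifnot(inherits(base, "complex_field"))
  frames <- lapply(seq_len(n_frames) - 1, function(k) {
    translate_field(base, dx = round(k * v[1]), dy = round(k * v[2]))
  })
  scene_sequence(frames, timestamps = (seq_len(n_frames) - 1) * frame_duration,
                 metadata = list(generator = "dynamic_sequence",
                                 velocity = v, seed = seed,
                                 frame_duration = frame_duration))
}

#' Scene sequence container
#' @param frames List of `complex_field` objects, all the same size.
#' @param timestamps Strictly increasing times in s, one per frame.
#' @param metadata Named list: generator name, parameters, seed.
#' @return A `scene_sequence`.
#' @export
scene_sequence <- function(frames, timestamps, metadata = list()) {
  stopifnot(length(frames) == length(timestamps))
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1 && any(dims != dims[, 1])) {
    stop("all frames must have the same dimensions", call. = FALSE)
  }
  structure(list(frames = frames, timestamps = timestamps, metadata = metadata),
            class = "scene_sequence")
}

#' @export
print.scene_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<scene_sequence> %d frame(s) of %d x %d px, t = %.6g .. %.6g s\n",
              length(x$frames), d[1], d[2],
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' @export
length.scene_sequence <- function(x) length(x$frames)
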