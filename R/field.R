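# Complex-field container: the object O(x_n, y_m) = A exp(i phi) and the
# reconstruction output.  Stored as an nx x ny complex matrix (rows = x).

#' Construct a complex field from amplitude and phase
#'
#' @param amplitude Nonnegative numeric matrix (nx rows = x, ny cols = y),
#'   or a scalar (recycled) together with `nx`/`ny`.
#' @param phase Phase in radians; matrix, scalar, or missing (0).  Wrapped to
#'   `(-pi, pi]`.
#' @param nx,ny Dimensions, required when `amplitude` is scalar.
#' @return A `complex_field` object (complex matrix).
#' @examples
#' f <- complex_field(1, pi / 3, nx = 4, ny = 5)
#' field_phase(f)[1, 1]
#' @export
complex_field <- function(amplitude, phase = 0, nx = NULL, ny = NULL) {
  if (is.matrix(amplitude)) {
    nx <- nrow(amplitude); ny <- ncol(amplitude)
  } else {
    if (is.null(nx) || is.null(ny)) {
      stop("scalar `amplitude` needs explicit `nx` and `ny`", call. = FALSE)
    }
    amplitude <- matrix(amplitude, nx, ny)
  }
  if (!is.matrix(phase)) phase <- matrix(phase, nx, ny)
  stopifnot(all(dim(phase) == c(nx, ny)))
  if (any(amplitude < 0)) stop("amplitude must be >= 0 everywhere", call. = FALSE)
  z <- amplitude * exp(1i * wrap_phase(phase))
  as_complex_field(z)
}

#' Coerce a complex matrix to a complex field
#' @param z Complex (or numeric) matrix.
#' @return A `complex_field`.
#' @export
as_complex_field <- function(z) {
  stopifnot(is.matrix(z))
  storage.mode(z) <- "complex"
  structure(z, class = c("complex_field", "matrix", "array"))
}

#' Wrap phase to the interval (-pi, pi]
#' @param phi Numeric (radians).
#' @return Wrapped phase.
#' @export
wrap_phase <- function(phi) pi - (pi - phi) %% (2 * pi)

#' Amplitude and phase images of a complex field
#' @param x A `complex_field` (or complex matrix).
#' @return Numeric matrix.
#' @export
field_amplitude <- function(x) {
  m <- Mod(unclass(x)); dimnames(m) <- NULL; m
}

#' @rdname field_amplitude
#' @export
field_phase <- function(x) {
  m <- Arg(unclass(x)); dimnames(m) <- NULL; m
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px, amplitude [%.4g, %.4g], phase [%.4g, %.4g] rad\n",
              nrow(x), ncol(x), min(field_amplitude(x)), max(field_amplitude(x)),
              min(field_phase(x)), max(field_phase(x))))
  invisible(x)
}

#' Translate a field with periodic wrap
#'
#' Shifts the image content by `dx` pixels along x (rows) and `dy` along y
#' (columns); pixels leaving one edge re-enter at the opposite edge.
#'
#' @param field A `complex_field`.
#' @param dx,dy Integer shifts in pixels.
#' @return Shifted `complex_field`.
#' @export
translate_field <- function(field, dx = 0, dy = 0) {
  nx <- nrow(field); ny <- ncol(field)
  i <- ((seq_len(nx) - 1 - round(dx)) %% nx) + 1
  j <- ((seq_len(ny) - 1 - round(dy)) %% ny) + 1
  as_complex_field(unclass(field)[i, j, drop = FALSE])
}
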