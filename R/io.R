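# File formats: raw binary traces with JSON sidecars, design JSON,
# 32-bit float TIFF images with scaling sidecars, CSV field dumps.
# All writes are atomic (write to a temp file in the target directory,
# then rename).

write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("atomic rename to '%s' failed", path), call. = FALSE)
  }
  invisible(path)
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
}

#' Write / read a detector trace (raw binary + JSON sidecar)
#'
#' Samples are stored little-endian: `int16` when the trace was digitized
#' (`bit_depth > 0`), `float32` otherwise.  A JSON sidecar at
#' `<path>.json` records sampling rate, sample count, dtype, start time,
#' bit depth, full scale and optional design reference / seed / scaling
#' metadata, making the pair self-describing.
#'
#' @param trace A `detector_trace`.
#' @param path Binary file path; the sidecar goes to `<path>.json`.
#' @param meta Optional named list merged into the sidecar (e.g.
#'   `design_ref`, `seed`, `frame_duration`, `n_frames`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, meta = list()) {
  stopifnot(inherits(trace, "detector_trace"))
  bd <- attr(trace, "bit_depth")
  dtype <- if (!is.null(bd) && bd > 0) "int16" else "float32"
  header <- c(list(
    format = "combfield-trace", version = 1L,
    dtype = dtype, endian = "little",
    n_samples = length(trace),
    sampling_rate = attr(trace, "sampling_rate"),
    start_time = attr(trace, "start_time"),
    bit_depth = if (is.null(bd)) 0L else bd,
    full_scale = attr(trace, "full_scale")
  ), meta)
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con), add = TRUE)
    if (dtype == "int16") {
      writeBin(as.integer(trace), con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(trace), con, size = 4L, endian = "little")
    }
  })
  write_json_atomic(header, paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_trace
#' @return For `read_trace()`: the `detector_trace`, with the sidecar
#'   attached as attribute `meta`.
#' @export
read_trace <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing trace sidecar '%s'", sidecar), call. = FALSE)
  }
  h <- tryCatch(jsonlite::read_json(sidecar, simplifyVector = TRUE),
                error = function(e) {
                  stop(sprintf("corrupt trace sidecar '%s': %s",
                               sidecar, conditionMessage(e)), call. = FALSE)
                })
  for (fld in c("dtype", "n_samples", "sampling_rate")) {
    if (is.null(h[[fld]])) {
      stop(sprintf("corrupt trace sidecar: field '%s' missing", fld),
           call. = FALSE)
    }
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- if (h$dtype == "int16") {
    readBin(con, "integer", n = h$n_samples, size = 2L, endian = "little")
  } else {
    readBin(con, "numeric", n = h$n_samples, size = 4L, endian = "little")
  }
  if (length(x) != h$n_samples) {
    stop("trace file shorter than its sidecar declares", call. = FALSE)
  }
  out <- detector_trace(x, sampling_rate = h$sampling_rate,
                        start_time = h$start_time %||% 0,
                        bit_depth = h$bit_depth %||% 0L)
  if (!is.null(h$full_scale) && !is.na(h$full_scale)) {
    attr(out, "full_scale") <- h$full_scale
  }
  attr(out, "meta") <- h
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a comb design as JSON
#'
#' Serializes both combs (axis, tones in Hz, band, spacing, offset, grid),
#' the carrier bookkeeping value `f0` and the analysis `bin_width`.  On
#' read, the spectral map is rebuilt from the tones, which are the
#' authoritative record.
#'
#' @param map A `spectral_map` (from [build_spectral_map()] or
#'   `default_design()$map`).
#' @param path JSON file path.
#' @return `path` invisibly; `read_design()` returns the `spectral_map`.
#' @export
write_design <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  ser_comb <- function(cb) {
    list(axis = cb$axis, tones = cb$tones, band_low = cb$band_low,
         band_high = cb$band_high, spacing = cb$spacing, offset = cb$offset,
         grid = cb$grid, device_band = cb$device_band)
  }
  write_json_atomic(list(
    format = "combfield-design", version = 1L,
    f0 = attr(map, "f0"), bin_width = attr(map, "bin_width"),
    comb_x = ser_comb(attr(map, "comb_x")),
    comb_y = ser_comb(attr(map, "comb_y"))
  ), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$format) || d$format != "combfield-design") {
    stop(sprintf("'%s' is not a comb design file", path), call. = FALSE)
  }
  de_comb <- function(cb) {
    structure(list(axis = cb$axis, tones = as.numeric(cb$tones),
                   band_low = cb$band_low, band_high = cb$band_high,
                   spacing = cb$spacing, offset = cb$offset, grid = cb$grid,
                   device_band = as.numeric(cb$device_band)),
              class = "freq_comb")
  }
  build_spectral_map(de_comb(d$comb_x), de_comb(d$comb_y),
                     f0 = d$f0, bin_width = d$bin_width)
}

#' Write / read a complex field as 32-bit float TIFFs
#'
#' Writes `<prefix>_amplitude.tif` and `<prefix>_phase.tif` plus a JSON
#' sidecar `<prefix>.json`.  Pixel values are stored normalized to [0, 1]
#' with the affine scaling (`offset`, `scale`, so that
#' `physical = offset + scale * stored`) recorded in the sidecar;
#' `read_field_tiff()` inverts it.
#'
#' @param field A `complex_field`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly; `read_field_tiff()` returns the
#'   `complex_field`.
#' @export
write_field_tiff <- function(field, prefix) {
  stopifnot(inherits(field, "complex_field"))
  planes <- list(amplitude = field_amplitude(field),
                 phase = field_phase(field))
  scaling <- list()
  for (nm in names(planes)) {
    m <- planes[[nm]]
    lo <- min(m); hi <- max(m)
    scale <- if (hi > lo) hi - lo else 1
    norm <- (m - lo) / scale
    write_atomic(sprintf("%s_%s.tif", prefix, nm), function(tmp) {
      tiff::writeTIFF(norm, tmp, bits.per.sample = 32L, reduce = FALSE)
    })
    scaling[[nm]] <- list(offset = lo, scale = scale)
  }
  write_json_atomic(list(format = "combfield-field", version = 1L,
                         nx = nrow(field), ny = ncol(field),
                         scaling = scaling),
                    paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(prefix) {
  h <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(nm) {
    m <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, nm))
    h$scaling[[nm]]$offset + h$scaling[[nm]]$scale * m
  }
  complex_field(rd("amplitude"), rd("phase"))
}

#' Dump a complex field to CSV
#'
#' Long-format CSV with columns `x`, `y`, `amplitude`, `phase`, `re`, `im`.
#'
#' @param field A `complex_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  df <- tidy(field)
  df$re <- Re(as.vector(unclass(field)))
  df$im <- Im(as.vector(unclass(field)))
  write_atomic(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
  invisible(path)
}

#' Write / read a calibration table as JSON
#'
#' @param calib A `calibration_table`.
#' @param path JSON path.
#' @return `path` invisibly; `read_calibration()` returns the table.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_table"))
  write_json_atomic(list(format = "combfield-calibration", version = 1L,
                         nx = nrow(calib), ny = ncol(calib),
                         source = attr(calib, "source"),
                         re = as.vector(Re(calib)),
                         im = as.vector(Im(calib))),
                    path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(d$format) || d$format != "combfield-calibration") {
    stop(sprintf("'%s' is not a calibration file", path), call. = FALSE)
  }
  structure(matrix(complex(real = d$re, imaginary = d$im), d$nx, d$ny),
            class = c("calibration_table", "matrix", "array"),
            source = d$source)
}
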