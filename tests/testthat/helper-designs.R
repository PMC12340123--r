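# Shared fixtures: small verified comb designs and field generators.
# The toy spacings/offsets were chosen (by exhaustive search over the 2 kHz
# grid) so that each toy passes verify_unique_mapping; the suite asserts
# this rather than trusting it.

# 8 x 9 pixels, tones on a 2 kHz grid near 2 MHz; min |beat| 10 kHz,
# max |beat| 578 kHz.  Grid-locked for 0.5/1/2/4 ms frames.
toy_map_8x9 <- function(bin_width = 1e3) {
  cx <- build_comb(2e6, 2e6 + 7 * 32e3, spacing = 32e3, grid = 2e3,
                   axis = "x", device_band = c(1e6, 5e6))
  cy <- build_comb(2e6, 2e6 + 42e3 + 8 * 66e3, spacing = 66e3, offset = 42e3,
                   grid = 2e3, axis = "y", device_band = c(1e6, 5e6))
  build_spectral_map(cx, cy, bin_width = bin_width)
}

# 16 x 17 pixels on the same grid; min |beat| 10 kHz, max 1.322 MHz.
toy_map_16x17 <- function(bin_width = 1e3) {
  cx <- build_comb(2e6, 2e6 + 15 * 80e3, spacing = 80e3, grid = 2e3,
                   axis = "x", device_band = c(1e6, 5e6))
  cy <- build_comb(2e6, 2e6 + 10e3 + 16 * 82e3, spacing = 82e3, offset = 10e3,
                   grid = 2e3, axis = "y", device_band = c(1e6, 5e6))
  build_spectral_map(cx, cy, bin_width = bin_width)
}

toy_acq <- function(...) {
  args <- list(...)
  defaults <- list(sampling_rate = 10e6, frame_duration = 1e-3,
                   E_R = 100, E_S = 1, E_1D = 0)
  do.call(acq_config, utils::modifyList(defaults, args))
}

flat_field <- function(map) {
  complex_field(1, 0, nx = attr(map, "nx"), ny = attr(map, "ny"))
}

random_field <- function(map, seed = 1) {
  nx <- attr(map, "nx"); ny <- attr(map, "ny")
  withr::with_seed(seed, {
    complex_field(matrix(runif(nx * ny, 0.2, 1), nx, ny),
                  matrix(runif(nx * ny, -3, 3), nx, ny))
  })
}

# Independent brute-force oracle for the mapping checks: all pixel pairs,
# mirror terms included via |beat|, plus DC / Nyquist / 1D-beat margins.
brute_force_check <- function(map, acq_nyquist, dc_guard) {
  ab <- abs(map$beat)
  bw <- attr(map, "bin_width") * (1 - 1e-9)
  n <- length(ab)
  collide <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(ab[i] - ab[j]) < bw) collide <- TRUE
    }
  }
  fx <- attr(map, "comb_x")$tones
  sep <- Inf
  if (length(fx) > 1) {
    d1 <- abs(outer(fx, fx, "-"))
    d1 <- d1[d1 > 0]
    sep <- min(abs(outer(ab, d1, "-")))
  }
  list(passed = !collide && min(ab) >= dc_guard && max(ab) < acq_nyquist &&
         sep >= bw,
       collide = collide, dc_margin = min(ab),
       nyquist_margin = acq_nyquist - max(ab), residual_1d_separation = sep)
}

max_complex_err <- function(a, b) max(Mod(unclass(a) - unclass(b)))
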