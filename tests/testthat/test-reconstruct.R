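test_that("fft_spectrum normalization: DC, on-grid cosine, Parseval", {
  fs <- 10e6
  # constant trace: all power in bin 0
  const <- detector_trace(rep(3.5, 10000), sampling_rate = fs)
  sp <- fft_spectrum(const)
  expect_equal(Mod(sp$values[1]), 3.5, tolerance = 1e-12)
  expect_lt(max(Mod(sp$values[-1])), 1e-10)

  # cosine of amplitude C on bin 77 reads C/2 there, nothing elsewhere
  t <- (0:9999) / fs
  C <- 1.8
  tr <- detector_trace(C * cos(2 * pi * 77e3 * t), sampling_rate = fs)
  sp <- fft_spectrum(tr)
  expect_equal(sp$bin_width, 1e3)
  expect_equal(Mod(sp$values[78]), C / 2, tolerance = 1e-12)
  expect_lt(max(Mod(sp$values[-78])), 1e-10)

  # Hann window with coherent-gain correction reads the same on-grid peak
  sph <- fft_spectrum(tr, window = "hann")
  expect_equal(Mod(sph$values[78]), C / 2, tolerance = 1e-10)

  # Parseval between trace power and two-sided spectral power
  x <- withr::with_seed(1, rnorm(4096))
  trx <- detector_trace(x, sampling_rate = fs)
  spx <- fft_spectrum(trx)
  v <- spx$values
  two_sided <- Mod(v[1])^2 + 2 * sum(Mod(v[2:(length(v) - 1)])^2) +
    Mod(v[length(v)])^2  # even length: Nyquist bin counted once
  expect_equal(sum(x^2) / length(x), two_sided, tolerance = 1e-10)
})

test_that("single-pixel extraction recovers amplitude and phase", {
  m1 <- build_spectral_map(build_comb(2e6, 2e6, 1e3, device_band = c(1e6, 5e6)),
                           build_comb(2.077e6, 2.077e6, 1e3, axis = "y",
                                      device_band = c(1e6, 5e6)))
  obj <- complex_field(1, pi / 3, nx = 1, ny = 1)
  acq <- toy_acq(E_R = 100, E_1D = 0)
  tr <- synthesize_trace(obj, m1, acq)
  raw <- reconstruct_frame(tr, m1)
  expect_equal(field_phase(raw)[1, 1], pi / 3, tolerance = 1e-2)
  calib <- null_calibrate(synthesize_trace(flat_field(m1), m1, acq), m1)
  rec <- reconstruct_frame(tr, m1, calib)
  expect_equal(field_amplitude(rec)[1, 1], 1, tolerance = 1e-2)
  expect_equal(field_phase(rec)[1, 1], pi / 3, tolerance = 1e-2)
})

test_that("negative-beat pixels come back through the conjugate bin", {
  # y tone below x tone: beat = -77 kHz
  m <- build_spectral_map(build_comb(2.077e6, 2.077e6, 1e3, device_band = c(1e6, 5e6)),
                          build_comb(2e6, 2e6, 1e3, axis = "y",
                                     device_band = c(1e6, 5e6)))
  expect_true(m$conjugate)
  obj <- complex_field(0.8, 1.1, nx = 1, ny = 1)
  acq <- toy_acq(E_R = 100, E_1D = 0)
  calib <- null_calibrate(synthesize_trace(flat_field(m), m, acq), m)
  rec <- reconstruct_frame(synthesize_trace(obj, m, acq), m, calib)
  expect_equal(field_amplitude(rec)[1, 1], 0.8, tolerance = 1e-2)
  expect_equal(field_phase(rec)[1, 1], 1.1, tolerance = 1e-2)
})

test_that("self-calibration maps the flat scene to exactly one", {
  map <- toy_map_8x9()
  acq <- toy_acq(E_1D = 0.2)
  flat_tr <- synthesize_trace(flat_field(map), map, acq)
  calib <- null_calibrate(flat_tr, map)
  rec <- reconstruct_frame(flat_tr, map, calib)
  expect_lt(max_complex_err(rec, flat_field(map)), 1e-10)
  # ideal uniform system: all factors equal
  expect_lt(max(Mod(unclass(calib) - unclass(calib)[1, 1])),
            1e-10 * Mod(unclass(calib)[1, 1]))
})

test_that("per-tone gain variation is cancelled by null calibration", {
  map <- toy_map_8x9()
  gain <- withr::with_seed(8, matrix(complex(
    modulus = runif(72, 0.5, 2), argument = runif(72, -pi, pi)), 8, 9))
  acq <- toy_acq(E_R = 100, E_1D = 0)
  flat_tr <- synthesize_trace(flat_field(map), map, acq, cross_terms = FALSE,
                              gain = gain)
  calib <- null_calibrate(flat_tr, map)
  # factors are proportional to the gain table
  ratio <- unclass(calib) / (gain * acq$E_S * acq$E_R)
  expect_lt(max(Mod(ratio - ratio[1, 1])), 1e-8)
  obj <- random_field(map, seed = 21)
  tr <- synthesize_trace(obj, map, acq, cross_terms = FALSE, gain = gain)
  rec <- reconstruct_frame(tr, map, calib)
  expect_lt(max_complex_err(rec, obj), 1e-8)
})

test_that("dead pixels are named by the calibration guard", {
  map <- toy_map_8x9()
  gain <- matrix(1 + 0i, 8, 9)
  gain[3, 4] <- 0
  tr <- synthesize_trace(flat_field(map), map, toy_acq(E_1D = 0), gain = gain)
  expect_error(null_calibrate(tr, map), "\\(3,4\\)")
})

test_that("full round trip at E_R/E_S = 1000 stays under 1e-3 relative error", {
  map <- toy_map_8x9()
  obj <- random_field(map, seed = 13)
  acq <- toy_acq(E_R = 1000, E_1D = 0.1)
  calib <- null_calibrate(synthesize_trace(flat_field(map), map, acq), map)
  rec <- reconstruct_frame(synthesize_trace(obj, map, acq), map, calib)
  rel <- Mod(unclass(rec) - unclass(obj)) / Mod(unclass(obj))
  expect_lt(max(rel), 1e-3)
})

test_that("extraction errors on out-of-band or missing-calibration input", {
  map <- toy_map_8x9()
  acq <- toy_acq(E_1D = 0)
  tr <- synthesize_trace(flat_field(map), map, acq)
  sp <- fft_spectrum(tr)
  sp_short <- sp
  sp_short$values <- sp$values[1:50]  # cut below max |beat| bin
  sp_short$n_bins <- 50L
  expect_error(extract_field(sp_short, map), "Nyquist")

  bad_calib <- structure(matrix(complex(real = NA), 8, 9),
                         class = c("calibration_table", "matrix", "array"),
                         source = "bad")
  expect_error(extract_field(sp, map, bad_calib), "missing|zero")
})

test_that("pure phase objects reconstruct with uniform amplitude", {
  map <- toy_map_16x17()
  obj <- phase_droplet_scene(16, 17, list(
    list(center = c(8, 9), radius = 5, peak_phase = pi / 2)))
  acq <- toy_acq(E_R = 1000, E_1D = 0)
  calib <- null_calibrate(synthesize_trace(flat_field(map), map, acq), map)
  rec <- reconstruct_frame(synthesize_trace(obj, map, acq), map, calib)
  # rigorous cross-term bound: each object-object pair whose difference
  # frequency lands on a signal bin biases that pixel by at most E_S/E_R
  # (unit amplitudes here), so the worst coincidence count sets the bound
  kk <- round(map$beat / attr(map, "bin_width"))
  dk <- abs(outer(kk, kk, "-"))
  worst <- max(vapply(abs(kk), function(ki) sum(dk == ki) / 2, numeric(1)))
  bound <- worst * acq$E_S / acq$E_R
  expect_lt(bound, 0.2)  # the toy design keeps the bias channel small
  expect_lt(max(abs(field_amplitude(rec) - 1)), bound)
  expect_lt(max(abs(wrap_phase(field_phase(rec) - field_phase(obj)))), bound)
})

test_that("streaming splits, reconstructs and truncates frames correctly", {
  map <- toy_map_8x9()
  obj <- random_field(map, seed = 4)
  acq <- toy_acq(E_R = 1000, E_1D = 0, n_frames = 10)
  calib <- null_calibrate(
    synthesize_trace(flat_field(map), map, toy_acq(E_R = 1000, E_1D = 0)), map)
  long <- synthesize_trace(obj, map, acq)
  seq <- stream_frames(long, map, calib, frame_duration = 1e-3)
  expect_length(seq, 10)
  expect_equal(seq$timestamps, (0:9) * 1e-3)
  for (f in seq$frames[-1]) {
    expect_lt(max_complex_err(f, seq$frames[[1]]), 1e-10)
  }

  # 1.5 frames: one frame survives, the partial tail is reported
  short <- detector_trace(as.numeric(long)[1:15000], sampling_rate = 10e6)
  expect_warning(seq2 <- stream_frames(short, map, calib, frame_duration = 1e-3),
                 "partial frame")
  expect_length(seq2, 1)
  expect_equal(seq2$metadata$dropped_samples, 5000)
  expect_error(stream_frames(detector_trace(rep(0, 100), sampling_rate = 10e6),
                             map, calib, frame_duration = 1e-3), "shorter")
})

test_that("cross-term contamination shrinks as the reference grows", {
  # the 16 x 17 toy has object-object difference frequencies landing on
  # signal bins, so the cross-term bias is visible and must shrink with E_R
  map <- toy_map_16x17()
  obj <- random_field(map, seed = 17)
  errs <- vapply(c(10, 100, 1000), function(er) {
    acq <- toy_acq(E_R = er, E_1D = 0)
    calib <- null_calibrate(synthesize_trace(flat_field(map), map, acq), map)
    rec <- reconstruct_frame(synthesize_trace(obj, map, acq), map, calib)
    mean(Mod(unclass(rec) - unclass(obj)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
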