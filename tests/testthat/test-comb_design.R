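test_that("build_comb fills the band per the spacing/offset contract", {
  comb <- build_comb(63e6, 88e6, spacing = 25e6 / 79)
  expect_length(comb$tones, 80)
  expect_equal(comb$tones[1], 63e6)
  expect_equal(comb$tones[80], 88e6)
  expect_true(all(diff(comb$tones) > 0))

  # degenerate band: a single tone
  expect_equal(build_comb(63e6, 63e6, 1e6)$tones, 63e6)

  # grid-locked comb: 313 kHz teeth on a 1 kHz grid
  g <- build_comb(63e6, 88e6, spacing = 313e3, grid = 1e3)
  expect_length(g$tones, 80)
  expect_equal(g$tones[80], 87.727e6)
  expect_true(all(abs(g$tones / 1e3 - round(g$tones / 1e3)) < 1e-9))
})

test_that("build_comb rejects empty, off-band and off-grid requests", {
  expect_error(build_comb(63e6, 64e6, spacing = 2e6, offset = 1.5e6), "empty")
  expect_error(build_comb(60e6, 88e6, spacing = 1e6), "device band")
  expect_error(build_comb(63e6, 88e6, spacing = 313.5e3, grid = 1e3), "grid")
  expect_error(build_comb(88e6, 63e6, spacing = 1e6), "band_end")
})

test_that("spectral map realizes beat = f_y - f_x with conjugate flags", {
  # two single-tone combs 25 MHz apart
  m1 <- build_spectral_map(build_comb(63e6, 63e6, 1e3),
                           build_comb(88e6, 88e6, 1e3, axis = "y"))
  expect_equal(m1$beat, 25e6)
  expect_false(m1$conjugate)

  # reversed: negative beat is flagged for conjugation
  m2 <- build_spectral_map(build_comb(88e6, 88e6, 1e3),
                           build_comb(63e6, 63e6, 1e3, axis = "y"))
  expect_equal(m2$beat, -25e6)
  expect_true(m2$conjugate)

  # identical symmetric combs: every diagonal pixel beats at zero
  cs <- build_comb(63e6, 63.5e6, spacing = 100e3)
  ms <- build_spectral_map(cs, build_comb(63e6, 63.5e6, 100e3, axis = "y"))
  diag_beats <- ms$beat[ms$n == ms$m]
  expect_true(all(diag_beats == 0))

  # packaged default: pixel (1,1) beats at the y-comb offset
  des <- default_design()
  expect_equal(des$map$beat[des$map$n == 1 & des$map$m == 1], 77e3)
  expect_identical(attr(des$map, "nx"), 80L)
  expect_identical(attr(des$map, "ny"), 81L)
})

test_that("verifier agrees with the brute-force pair oracle", {
  # collision-free 3 x 4 toy
  cx <- build_comb(2e6, 2e6 + 2 * 100e3, 100e3, device_band = c(1e6, 5e6))
  cy <- build_comb(2e6, 2e6 + 11e3 + 3 * 130e3, 130e3, offset = 11e3,
                   axis = "y", device_band = c(1e6, 5e6))
  map <- build_spectral_map(cx, cy, bin_width = 1e3)
  got <- verify_unique_mapping(map, acq_nyquist = 5e6, dc_guard = 5e3)
  want <- brute_force_check(map, acq_nyquist = 5e6, dc_guard = 5e3)
  expect_true(got$passed)
  expect_equal(got$passed, want$passed)
  expect_equal(got$dc_margin, want$dc_margin)
  expect_equal(got$nyquist_margin, want$nyquist_margin)
  expect_equal(got$residual_1d_separation, want$residual_1d_separation)

  # both toys used across the suite must verify
  for (map in list(toy_map_8x9(), toy_map_16x17())) {
    got <- verify_unique_mapping(map, acq_nyquist = 5e6, dc_guard = 5e3)
    want <- brute_force_check(map, acq_nyquist = 5e6, dc_guard = 5e3)
    expect_true(got$passed)
    expect_equal(got$dc_margin, want$dc_margin)
    expect_equal(got$residual_1d_separation, want$residual_1d_separation)
  }
})

test_that("verifier reports failures instead of raising", {
  # equal symmetric combs: diagonal zero beats collide and sit on DC
  cs <- build_comb(63e6, 64e6, spacing = 250e3)
  ms <- build_spectral_map(cs, build_comb(63e6, 64e6, 250e3, axis = "y"))
  rep <- verify_unique_mapping(ms, acq_nyquist = 25e6, dc_guard = 50e3)
  expect_false(rep$passed)
  expect_gt(nrow(rep$collisions), 0)
  expect_equal(rep$dc_margin, 0)

  # single-pixel map cannot collide
  m1 <- build_spectral_map(build_comb(63e6, 63e6, 1e3),
                           build_comb(63.077e6, 63.077e6, 1e3, axis = "y"))
  rep1 <- verify_unique_mapping(m1, acq_nyquist = 25e6, dc_guard = 10e3)
  expect_true(rep1$passed)
  expect_equal(rep1$dc_margin, 77e3)
})

test_that("a passing map is injective in |beat| (brute force)", {
  for (map in list(toy_map_8x9(), toy_map_16x17())) {
    ab <- abs(map$beat)
    n <- length(ab)
    for (i in seq_len(n - 1)) {
      expect_true(all(abs(ab[i] - ab[(i + 1):n]) >= attr(map, "bin_width") * (1 - 1e-9)))
    }
    # mirror safety: no pixel pair with beat_i = -beat_j
    expect_false(any(outer(map$beat, -map$beat, "==")[upper.tri(diag(n))]))
  }
})

test_that("default design verifies and is grid-locked to the frame bin", {
  des <- default_design()
  g <- glance(des$report)
  expect_true(g$passed)
  expect_identical(g$n_collisions, 0L)
  expect_gte(g$dc_margin, 50e3)
  expect_gt(g$nyquist_margin, 0)
  expect_gte(g$residual_1d_separation, 1e3)
  # every beat an exact integer multiple of the 1 kHz FFT bin
  k <- des$map$beat / attr(des$map, "bin_width")
  expect_true(all(abs(k - round(k)) < 1e-9))
})

test_that("design JSON round-trips through write_design/read_design", {
  map <- toy_map_8x9()
  path <- withr::local_tempfile(fileext = ".json")
  write_design(map, path)
  back <- read_design(path)
  expect_equal(back$beat, map$beat)
  expect_equal(attr(back, "nx"), attr(map, "nx"))
  expect_equal(attr(back, "bin_width"), attr(map, "bin_width"))
  expect_equal(attr(back, "comb_y")$tones, attr(map, "comb_y")$tones)
})
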