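# Forward model: the single-pixel detector time series produced by the
# comb-encoded illumination after a complex-valued object.
#
# Everything is synthesized at baseband: the optical carrier (~291 THz at
# 1030 nm) is never represented because the detected intensity contains only
# difference frequencies.  The residual 1D-diffraction light is
# polarization-separated from the reference/signal path, so it adds
# incoherently: I(t) = |E_R + E_S sum O exp(i 2 pi beat t)|^2
#                     + E_1D^2 |sum_n exp(i 2 pi (f_x(n) - f_x(1)) t)|^2.
# Its squared modulus depends only on the f_x differences, so shifting the
# residual comb to baseband changes nothing.

#' Acquisition / detector configuration
#'
#' @param sampling_rate Digitizer rate in Sa/s.
#' @param frame_duration Analysis frame duration in s.
#' @param n_frames Number of consecutive frames to synthesize.
#' @param E_R Reference (unmodulated carrier) amplitude, detector units.
#'   The reference is much stronger than a single tone in practice; default
#'   100 x `E_S`.
#' @param E_S Per-tone signal amplitude.
#' @param E_1D Residual 1D-diffraction amplitude; 0 disables that term.
#' @param noise_sigma Additive Gaussian noise std, detector units.
#' @param shot_noise If `TRUE`, adds zero-mean noise with per-sample std
#'   `sqrt(max(sample, 0))` (Gaussian approximation to photon noise at the
#'   detector's analog output).
#' @param bit_depth Digitizer bits (signed); 0 = ideal float detector.
#' @param full_scale Detector units spanning the positive half-range of the
#'   digitizer; `NA` auto-scales so the trace peak sits at 50% of range.
#' @param rng_seed Integer seed for noise generation.
#' @return An `acq_config` list.
#' @export
acq_config <- function(sampling_rate = 50e6, frame_duration = 1e-3,
                       n_frames = 1, E_R = 100, E_S = 1, E_1D = 0.1,
                       noise_sigma = 0, shot_noise = FALSE, bit_depth = 0,
                       full_scale = NA_real_, rng_seed = 1L) {
  stopifnot(sampling_rate > 0, frame_duration > 0, n_frames >= 1,
            E_R >= 0, E_S >= 0, E_1D >= 0, noise_sigma >= 0, bit_depth >= 0)
  structure(
    list(sampling_rate = sampling_rate, frame_duration = frame_duration,
         n_frames = as.integer(n_frames), E_R = E_R, E_S = E_S, E_1D = E_1D,
         noise_sigma = noise_sigma, shot_noise = isTRUE(shot_noise),
         bit_depth = as.integer(bit_depth), full_scale = full_scale,
         rng_seed = as.integer(rng_seed)),
    class = "acq_config"
  )
}

#' Detector trace container
#' @param samples Real-valued sample vector, detector units (or integer
#'   codes when digitized).
#' @param sampling_rate Sa/s.
#' @param start_time s.
#' @param bit_depth Digitizer bits used to produce `samples` (0 = float).
#' @return A `detector_trace`.
#' @export
detector_trace <- function(samples, sampling_rate, start_time = 0,
                           bit_depth = 0L) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sampling_rate > 0)
  structure(as.numeric(samples),
            sampling_rate = sampling_rate, start_time = start_time,
            bit_depth = as.integer(bit_depth), class = "detector_trace")
}

#' @export
print.detector_trace <- function(x, ...) {
  cat(sprintf("<detector_trace> %d samples @ %.6g MSa/s (%.6g ms), range [%.4g, %.4g]\n",
              length(x), attr(x, "sampling_rate") / 1e6,
              length(x) / attr(x, "sampling_rate") * 1e3,
              min(x), max(x)))
  invisible(x)
}

# Accumulate complex values into spectrum bins, summing duplicates.
# idx is 0-based (already reduced mod length(spec)).
accum_bins <- function(spec, idx, val) {
  s <- rowsum(cbind(Re(val), Im(val)), idx, reorder = FALSE)
  i <- as.integer(rownames(s)) + 1L
  spec[i] <- spec[i] + complex(real = s[, 1], imaginary = s[, 2])
  spec
}

# Synthesize sum_p c_p exp(i 2 pi f_p t) over one frame of n_samp samples at
# rate fs.  Uses an inverse FFT when all frequencies are on the fs/n_samp
# grid, otherwise evaluates the sum directly (guarded against huge cases).
synth_field_frame <- function(freqs, coefs, n_samp, fs) {
  bin <- fs / n_samp
  k <- freqs / bin
  if (max(abs(k - round(k))) < 1e-6) {
    spec <- complex(length.out = n_samp)
    spec <- accum_bins(spec, round(k) %% n_samp, coefs)
    fft(spec, inverse = TRUE)
  } else {
    if (length(freqs) * n_samp > 5e7) {
      stop("off-grid synthesis too large; grid-lock the design or reduce size",
           call. = FALSE)
    }
    t <- (seq_len(n_samp) - 1) / fs
    S <- complex(length.out = n_samp)
    for (p in seq_along(freqs)) {
      S <- S + coefs[p] * exp(2i * pi * freqs[p] * t)
    }
    S
  }
}

#' Synthesize the single-pixel detector trace
#'
#' Computes the noiseless detector intensity for a complex object under the
#' comb encoding.  `mode = "direct"` squares the summed fields:
#' `I(t) = |E_R + E_S sum O exp(i 2 pi beat t)|^2 + E_1D^2 |sum_n exp(i 2 pi
#' df_x(n) t)|^2` (the residual 1D diffraction is polarization-separated
#' from the signal path and adds incoherently).  `mode = "expanded"`
#' evaluates the term-by-term cosine expansion of the same intensity — DC
#' terms, signal beats `2 E_S E_R A cos(2 pi beat t + phi)`, object-object
#' cross terms `2 E_S^2 Re(O_p O_q* exp(i 2 pi (beat_p - beat_q) t))`, and
#' 1D-1D beats.  The two modes agree to floating-point precision; the direct
#' squared magnitude serves as the oracle for the expansion.  Noise and
#' digitization are NOT applied here; see [apply_noise_and_digitize()].
#'
#' With a grid-locked design the trace is periodic with the frame duration,
#' so `n_frames > 1` tiles one synthesized frame.
#'
#' @param object A `complex_field` with the map's dimensions.
#' @param map A [build_spectral_map()] result.
#' @param acq An [acq_config()].
#' @param mode `"direct"` or `"expanded"`.
#' @param cross_terms If `FALSE`, object-object cross terms are omitted
#'   (idealized linear encoding; both modes honour the flag).
#' @param gain Optional complex per-pixel gain matrix modelling tone-to-tone
#'   amplitude/phase variation (removable by null calibration).
#' @return A noiseless `detector_trace`.
#' @export
synthesize_trace <- function(object, map, acq, mode = c("direct", "expanded"),
                             cross_terms = TRUE, gain = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(object, "complex_field"), inherits(map, "spectral_map"),
            inherits(acq, "acq_config"))
  nx <- attr(map, "nx"); ny <- attr(map, "ny")
  if (nrow(object) != nx || ncol(object) != ny) {
    stop(sprintf("object is %d x %d but map is %d x %d",
                 nrow(object), ncol(object), nx, ny), call. = FALSE)
  }
  fs <- acq$sampling_rate
  if (fs <= 2 * max(abs(map$beat))) {
    stop("sampling rate below Nyquist of the largest |beat|", call. = FALSE)
  }
  fx <- attr(map, "comb_x")$tones
  dfx <- fx - fx[1]
  if (acq$E_1D > 0 && length(dfx) > 1 && fs <= 2 * max(dfx)) {
    stop("sampling rate below Nyquist of the largest 1D-diffraction beat",
         call. = FALSE)
  }
  n_samp <- round(fs * acq$frame_duration)
  if (n_samp < 2) stop("frame too short", call. = FALSE)

  grid_ok <- is_grid_locked(map$beat, fs / n_samp) &&
    (acq$E_1D == 0 || length(dfx) <= 1 || is_grid_locked(dfx, fs / n_samp))
  if (acq$n_frames > 1 && !grid_ok) {
    # off-grid tones are not frame-periodic: evaluate the full record at once
    acq1 <- acq
    acq1$n_frames <- 1L
    acq1$frame_duration <- acq$frame_duration * acq$n_frames
    return(synthesize_trace(object, map, acq1, mode, cross_terms, gain))
  }

  # per-pixel complex coefficients in map (column-major) order
  cp <- acq$E_S * as.vector(unclass(object))
  if (!is.null(gain)) {
    stopifnot(all(dim(gain) == c(nx, ny)))
    cp <- cp * as.vector(gain)
  }

  frame <- if (mode == "direct") {
    S <- if (cross_terms) {
      synth_field_frame(map$beat, cp, n_samp, fs)
    } else {
      NULL
    }
    if (cross_terms) {
      I <- Mod(acq$E_R + S)^2
    } else {
      # linearized: DC + signal beats only (term-wise, cross terms dropped)
      I <- expanded_frame(map, cp, acq, n_samp, fs, cross_terms = FALSE,
                          include_1d = FALSE)
    }
    if (acq$E_1D > 0 && length(dfx) >= 1) {
      S1 <- synth_field_frame(dfx, rep(1 + 0i, length(dfx)), n_samp, fs)
      I <- I + acq$E_1D^2 * Mod(S1)^2
    }
    I
  } else {
    expanded_frame(map, cp, acq, n_samp, fs, cross_terms = cross_terms,
                   include_1d = acq$E_1D > 0)
  }
  detector_trace(rep(frame, acq$n_frames), sampling_rate = fs)
}

is_grid_locked <- function(freqs, bin) {
  max(abs(freqs / bin - round(freqs / bin))) < 1e-6
}

# Term-by-term evaluation of the full cosine expansion over one frame.
expanded_frame <- function(map, cp, acq, n_samp, fs, cross_terms = TRUE,
                           include_1d = TRUE) {
  fx <- attr(map, "comb_x")$tones
  nx1d <- length(fx)
  dc <- acq$E_R^2 + sum(Mod(cp)^2) +
    (if (include_1d) nx1d * acq$E_1D^2 else 0)

  freqs <- map$beat
  coefs <- acq$E_R * cp            # signal beats: 2 E_R Re(c_p e^{i b t})
  bin <- fs / n_samp
  on_grid <- is_grid_locked(freqs, bin) &&
    (!include_1d || nx1d <= 1 || is_grid_locked(fx - fx[1], bin))

  if (on_grid) {
    spec <- complex(length.out = n_samp)
    kk <- round(freqs / bin)
    spec <- accum_bins(spec, kk %% n_samp, coefs)
    spec <- accum_bins(spec, (-kk) %% n_samp, Conj(coefs))
    if (cross_terms && length(cp) > 1) {
      P <- length(cp)
      for (p in seq_len(P - 1)) {
        q <- (p + 1):P
        z <- cp[p] * Conj(cp[q])
        dk <- kk[p] - kk[q]
        spec <- accum_bins(spec, dk %% n_samp, z)
        spec <- accum_bins(spec, (-dk) %% n_samp, Conj(z))
      }
    }
    if (include_1d && nx1d > 1) {
      k1 <- round((fx - fx[1]) / bin)
      for (p in seq_len(nx1d - 1)) {
        q <- (p + 1):nx1d
        dk <- k1[p] - k1[q]
        e <- rep(acq$E_1D^2 + 0i, length(q))
        spec <- accum_bins(spec, dk %% n_samp, e)
        spec <- accum_bins(spec, (-dk) %% n_samp, e)
      }
    }
    dc + Re(fft(spec, inverse = TRUE))
  } else {
    P <- length(cp)
    n_terms <- P + (if (cross_terms) P * (P - 1) / 2 else 0) +
      (if (include_1d) nx1d * (nx1d - 1) / 2 else 0)
    if (n_terms * n_samp > 5e7) {
      stop("off-grid expanded synthesis too large; grid-lock the design",
           call. = FALSE)
    }
    t <- (seq_len(n_samp) - 1) / fs
    I <- rep(dc, n_samp)
    for (p in seq_len(P)) {
      I <- I + 2 * Re(coefs[p] * exp(2i * pi * freqs[p] * t))
    }
    if (cross_terms && P > 1) {
      for (p in seq_len(P - 1)) {
        for (q in (p + 1):P) {
          I <- I + 2 * Re(cp[p] * Conj(cp[q]) *
                            exp(2i * pi * (freqs[p] - freqs[q]) * t))
        }
      }
    }
    if (include_1d && nx1d > 1) {
      for (p in seq_len(nx1d - 1)) {
        for (q in (p + 1):nx1d) {
          I <- I + 2 * acq$E_1D^2 * cos(2 * pi * (fx[p] - fx[q]) * t)
        }
      }
    }
    I
  }
}

#' Apply detector noise and digitization to a trace
#'
#' Adds Gaussian read noise (`noise_sigma`), optional shot-like noise with
#' per-sample std `sqrt(max(sample, 0))`, and, when `bit_depth > 0`, scales
#' by `full_scale` and rounds to signed integer codes with saturation.  A
#' saturation fraction above 1% raises a warning.  Deterministic under
#' `acq$rng_seed`.
#'
#' @param trace A `detector_trace`.
#' @param acq An [acq_config()]; fields `noise_sigma`, `shot_noise`,
#'   `bit_depth`, `full_scale`, `rng_seed` are used.
#' @return A `detector_trace`; digitized traces carry attributes
#'   `full_scale` and `saturation_fraction`.
#' @export
apply_noise_and_digitize <- function(trace, acq) {
  stopifnot(inherits(trace, "detector_trace"), inherits(acq, "acq_config"))
  x <- as.numeric(trace)
  withr::with_seed(acq$rng_seed, {
    if (acq$shot_noise) {
      x <- x + rnorm(length(x), sd = sqrt(pmax(x, 0)))
    }
    if (acq$noise_sigma > 0) {
      x <- x + rnorm(length(x), sd = acq$noise_sigma)
    }
  })
  sat_frac <- 0
  fs_used <- NA_real_
  if (acq$bit_depth > 0) {
    half <- 2^(acq$bit_depth - 1)
    fs_used <- if (is.na(acq$full_scale)) 2 * max(abs(x)) else acq$full_scale
    codes <- round(x / fs_used * half)
    sat <- codes < -half | codes > half - 1
    sat_frac <- mean(sat)
    codes <- pmin(pmax(codes, -half), half - 1)
    if (sat_frac > 0.01) {
      warning(sprintf("digitizer saturation on %.2f%% of samples",
                      100 * sat_frac), call. = FALSE)
    }
    x <- codes
  }
  out <- detector_trace(x, sampling_rate = attr(trace, "sampling_rate"),
                        start_time = attr(trace, "start_time"),
                        bit_depth = acq$bit_depth)
  attr(out, "full_scale") <- fs_used
  attr(out, "saturation_fraction") <- sat_frac
  out
}

#' Multiply an object by a random thin phase screen
#'
#' Emulates a static thin scattering screen in the detection path: each
#' pixel's phase is shifted by `strength * u`, `u ~ Uniform(-pi, pi)`
#' i.i.d. under `seed`; amplitudes are unchanged.  Because detection is a
#' coherent per-tone sum, a null calibration acquired through the same
#' screen cancels it exactly.
#'
#' @param object A `complex_field`.
#' @param seed Integer seed.
#' @param strength Screen strength in `[0, 1]`.
#' @return A `complex_field`.
#' @export
apply_phase_screen <- function(object, seed, strength = 1) {
  stopifnot(inherits(object, "complex_field"))
  if (strength < 0 || strength > 1) stop("`strength` must be in [0, 1]", call. = FALSE)
  u <- withr::with_seed(seed,
                        matrix(runif(length(object), -pi, pi),
                               nrow(object), ncol(object)))
  as_complex_field(unclass(object) * exp(1i * strength * u))
}
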