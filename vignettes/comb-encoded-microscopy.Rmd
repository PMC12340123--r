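---
title: "Comb-encoded single-pixel complex-field microscopy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comb-encoded single-pixel complex-field microscopy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combfield)
```

## The measurement model

A pair of crossed acousto-optic deflectors (AODs), driven by radio-frequency
combs, fans a coherent beam into an `N x M` grid of sub-beams.  The x-axis
deflector downshifts the optical frequency by its drive tone `f_x(n)` and the
y-axis deflector upshifts by `f_y(m)`, so the pixel at `(n, m)` illuminates
the sample with optical frequency

```
f(n, m) = f0 - f_x(n) + f_y(m),
```

where `f0` is the frequency of the unmodulated (zero-order) component that is
kept as a coaxial reference.  After the transparent object
`O(n, m) = A exp(i phi)` and interference with the reference, a single
photodetector records

```
I(t) = | E_R + E_S * sum_{n,m} O(n,m) exp(i 2 pi beat(n,m) t) |^2
       + E_1D^2 * | sum_n exp(i 2 pi df_x(n) t) |^2,
beat(n, m) = f_y(m) - f_x(n).
```

Everything is written at baseband: the optical carrier (~291 THz at 1030 nm)
cancels in the detected intensity, which contains only difference
frequencies.  The second modulus is the residual one-dimensional diffraction
— light deflected by only the first AOD.  It is polarization-separated from
the reference/signal path, so it adds *incoherently*: its expansion contains
only the pairwise `f_x` difference tones, never `E_1D x E_R` beats.  (Summing
all three fields inside one modulus would instead predict beats at the raw
`f_x` drive frequencies, 63–88 MHz, which alias at the 50 MSa/s digitizer and
are not present in the detected signal.)

Expanding the first modulus gives the term structure the simulator exposes in
its `expanded` mode:

* DC: `E_R^2 + E_S^2 sum A^2 (+ N * E_1D^2)`;
* signal beats: `2 E_S E_R A cos(2 pi beat t + phi)` — one per pixel, each at
  its own beat frequency;
* object–object cross terms:
  `2 E_S^2 Re(O_p O_q^* exp(i 2 pi (beat_p - beat_q) t))` over unordered
  pixel pairs;
* 1D–1D beats: `2 E_1D^2 cos(2 pi (f_x(n) - f_x(n')) t)`.

The `direct` mode evaluates the squared magnitudes literally and serves as
the oracle for the expansion; the two agree to better than `1e-10` relative
error (this is asserted in the test suite, not assumed).  Note that the
cross-term sum must run over *unordered* pairs with the full complex product
`O_p O_q^*` — keeping only its real part against a cosine, or summing ordered
pairs, double-counts and discards the quadrature component, and would not
match the squared magnitude.

One FFT of a frame then demodulates every pixel at once: with the
normalization `values = FFT / length`, the bin at `|beat|/bin_width` holds
`E_S E_R O(n, m)` (conjugated when `beat < 0`), and dividing by a
null-calibration table turns that into `O(n, m)` itself.

## Designing a collision-free encoding

The mapping is usable only if every pixel owns a spectral bin of its own.
Because the detector records a *real* signal, positive and negative beats
fold onto `|beat|`; the design constraints are therefore:

1. all `|beat|` values pairwise distinct by at least one analysis bin
   (`1/frame duration`) — this covers the mirror condition
   `beat_i = -beat_j` as well;
2. `min |beat|` clear of the DC term by a guard band (50 kHz default);
3. `max |beat|` below the acquisition Nyquist frequency;
4. every `|beat|` at least one bin away from every 1D-diffraction beat
   `|f_x(n) - f_x(n')|`.

`verify_unique_mapping()` checks all four exhaustively (sorting reduces the
pairwise check to adjacent gaps, which is equivalent) and *reports* failures
with the offending pixel pairs rather than silently perturbing the comb — a
deliberate tie-break policy: encodings are corrected by redesign, not by
hidden nudges.

The packaged default is an 80 x 81 encoding on a 1 kHz grid (leakage-free
for 1 ms frames at 50 MSa/s):

* `comb_x`: 63 MHz + k·307 kHz, k = 0…79 (top tone 87.253 MHz);
* `comb_y`: 63 MHz + 77 kHz + k·309 kHz, k = 0…80 (top tone 87.797 MHz);

both inside the 61–91 MHz device band.  The coprime spacings (307 is prime)
forbid exact beat repeats, and the 77 kHz common shift breaks the mirror
symmetry.  The margins are: `min |beat|` = 74 kHz (DC guard 50 kHz),
`max |beat|` = 24.797 MHz (Nyquist 25 MHz), worst 1D-beat separation 70 kHz.
Neighbouring parameter choices are *not* interchangeable: for example,
moving the x-spacing to 313 kHz (same tone counts, same shift) produces a
mapping whose smallest `|beat|` is a single kilohertz — numerically unique,
but sitting on top of the DC pedestal and useless in practice.  This is why
`default_design()` re-runs the verifier at construction time and refuses to
return an unverified encoding.

With the comb grid equal to the FFT bin width, every beat lands on an exact
bin, so rectangular-window extraction has no spectral leakage and no window
is needed.  A Hann window (with its coherent-gain correction) is provided
for externally recorded traces whose tones are off-grid; extraction then
uses nearest-bin lookup and says so.

## Null calibration

Real systems have tone-to-tone amplitude and phase variation (RF
amplification flatness, diffraction efficiency, path lengths).  All of it is
multiplicative and static, so a single acquisition of a featureless scene
measures the per-pixel complex system response `E_S E_R g(n, m)`;
`null_calibrate()` stores those raw values and `extract_field()` divides by
them.  The same mechanism removes a static thin scattering screen in the
detection path (`apply_phase_screen()`): the screen multiplies each pixel's
coefficient by a unit phasor, which cancels between the null and the object
acquisition.  Calibration factors near zero indicate dead pixels and are an
error, not a silent division.

## Noise and digitization

Read noise is additive Gaussian (`noise_sigma`, detector units).  Shot noise
is approximated as Gaussian with per-sample standard deviation
`sqrt(max(sample, 0))`, i.e. photon-count-like units at the analog output;
exact Poisson statistics are out of scope.  The digitizer model rounds to
signed `bit_depth`-bit codes at a configurable full scale (auto-scaled so
the peak sits at half range when unset, mirroring common practice with
16-bit acquisition cards), counts saturated samples, and warns when more
than 1% saturate.  All noise is generated under an explicit seed; identical
configurations produce bit-identical traces.

Because a calibrated pixel value is a single FFT bin, its noise standard
deviation scales as `sigma / sqrt(frame samples)` — doubling the frame
duration buys `sqrt(2)` in pixel SNR at the cost of halving the frame rate.
The Monte-Carlo check in the suite verifies the `1/sqrt(T)` law over
0.5–4 ms frames within 20%.

## What limits accuracy: object–object cross terms

The object–object terms beat at *differences* of pixel beats, and nothing
forbids such a difference from landing on another pixel's signal bin.  Each
coincident pair biases that pixel by at most `E_S |O_p O_q| / E_R` after
calibration, so the contamination scales with the worst per-bin coincidence
count times `E_S/E_R` — which is why the reference is kept much stronger
than a single tone (default `E_R/E_S = 100`, configurable; the instrument
class this models does the same optically).  The suite asserts both the
rigorous per-bin bound and the monotone decrease of the error over
`E_R/E_S` in {10, 100, 1000}.  At the full 80 x 81 frame size the
coincidence counts are large (thousands of pairs per bin), so quantitative
work at modest reference strength should either disable cross terms (the
idealized linear encoding, `cross_terms = FALSE`) or budget for the bias;
the exact-recovery guarantees quoted below are stated for the linear model.

Interestingly, small encodings can avoid the effect entirely: the 8 x 9 toy
design used throughout the tests happens to have *no* object–object
difference landing on any signal bin, so its round trips are exact at any
reference strength, while the 16 x 17 toy does exhibit the bias and is used
to test it.

## Synthetic scenes

`bar_target()` builds a three-bar USAF-style element (bar width = gap,
length 5x width) for resolution checks; `profile_dips()` confirms an element
is resolved when exactly three prominent minima appear across the bars.
`phase_droplet_scene()` emulates transparent droplets with an index
contrast: amplitude 1 everywhere and a spherical-cap phase profile
`peak * sqrt(1 - r^2/R^2)` — the phase a plane wave accumulates through a
spherical droplet of uniform index, with pi/2 peak by default so wrapped
reconstructions stay unambiguous.  `mixing_gradient_scene()` models two
solutions meeting at a diffusing interface as an error-function phase ramp
whose width grows with time.  `dynamic_sequence()` translates any of these
with periodic wrap for streaming tests.

These generators emulate the *structure* of real targets (bars, droplets,
gradients), not their physics: there is no fluid dynamics, no absorption
spectrum, no speckle, and the phase screen is a single static thin layer.
Passing round trips therefore demonstrate the correctness of the
encode–decode chain, not instrument performance on real scenes.

## Figures of merit

* `cnr()` — (mean target − mean background) / background SD on an amplitude
  image.  As defined it is invariant under gain and offset of the whole
  image (both numerator and denominator scale), which the tests assert.
* `sbpt()` — frames/s x pixels, times 2 when amplitude and phase both count
  as information channels.  Headline values are conventionally quoted at two
  significant figures (`sbpt_printed()`); with the 2-channel convention the
  80 x 81 @ 1000 Hz system reaches 1.3e7.
* `usaf_linewidth()` — group g, element e resolves `2^(g+(e-1)/6)` lp/mm;
  group 7-1 bars are 3.91 um.
* `pixel_pitch_and_fov()` — an AOD deflects by `theta = lambda f / V`, so one
  comb step advances the focal spot by
  `f_obj * lambda * (span/(tones-1)) / V`.  With lambda = 1030 nm,
  f_obj = 7.5 mm, a 25 MHz span over 79 steps and V = 650 m/s this gives a
  3.76 um pitch and a 297 um field of view.  The acoustic velocity is *not*
  a measured quantity here: 650 m/s is the slow-shear TeO2 value typical of
  this deflector class, clearly labelled as an assumption and configurable.
* `time_bandwidth_product()` — aperture transit time x bandwidth,
  `(D/V) * span`; about 192 for a 5 mm beam, comfortably above the 80–81
  resolvable spots per axis the combs request.

## Numerical choices

* **Synthesis.** When every tone sits on the FFT grid the field sum is
  assembled in the frequency domain and inverse-transformed (exact and
  O(N log N)); the term-by-term `expanded` mode accumulates each cosine's
  two half-amplitude spectral lines the same way.  Off-grid tones fall back
  to direct time-domain evaluation, guarded against absurd sizes.  A
  grid-locked multi-frame acquisition of a static scene is periodic with
  the frame, so one frame is synthesized and tiled.
* **Extraction.** Bins are addressed by `round(|beat|/bin_width)`; more than
  half a bin off-grid is an error, anything measurably off-grid is logged.
  Phase is reported wrapped to (-pi, pi]; no unwrapping is attempted.
* **Frames** are independent and non-overlapping; a trailing partial frame
  is dropped with a warning carrying the sample count.
* **Tolerances.** Exactness claims in the tests are `1e-10` per-pixel
  complex error (double-precision FFT round trips leave ~1e-15 headroom);
  the dead-pixel guard is `1e-6` of the largest calibration modulus.
* **Problem sizes.** The suite exercises the full 80 x 81 frame for design
  verification, exact round trips and a one-second 1000-frame stream
  (5e7 samples), and uses the verified 8 x 9 / 16 x 17 toy encodings for
  properties where frame size is irrelevant; the noise-scaling Monte Carlo
  uses 24 frames per duration.  These sizes were chosen as the smallest
  that make each property visible.

## Known limitations

* Polarization optics, grating convergence, Bragg-angle geometry and AOD
  efficiency-vs-frequency are not modelled; their net effect on the signal
  path is a per-pixel complex gain, which calibration removes.
* The scattering screen is a static thin phase mask at the detection side;
  volumetric or time-varying scattering is out of scope.
* Shot noise is Gaussian, not Poisson.
* Compressive or regularized reconstruction is out of scope: decoding is
  one FFT plus indexed extraction, by design.
* Measured contrast-to-noise ratios on real instrument images depend on the
  experimental data and are not reproduced here; `cnr()` implements the
  metric itself.
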