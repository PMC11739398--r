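---
title: "Modulation- and propagation-based phase-contrast micro-CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation- and propagation-based phase-contrast micro-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpci)
```

## Scope

`xpci` implements a complete analysis chain for X-ray phase-contrast
micro-tomography of weakly absorbing specimens (the motivating application
is paraffin-embedded soft tissue such as placental villous trees), together
with a wave-optics virtual beamline that generates fully synthetic datasets
with known ground truth. Two imaging modes are covered:

* **MBI (modulation-based imaging)**: a wavefront marker — a hexagonal
  Talbot array illuminator (TAI) phase grating or a stack of sandpaper
  sheets — imprints a high-contrast intensity pattern on the beam. The
  specimen distorts this pattern; windowed least-squares pattern matching
  recovers, per pixel, the transmission `T`, the pattern displacement
  `(u_x, u_y)` and the dark-field `D`.
* **PBI (propagation-based imaging)**: free-space propagation alone turns
  phase gradients into edge fringes, inverted with a single-distance
  low-pass (Paganin-type) filter.

Everything downstream of the raw frames is shared: dark/flat and
beam-profile correction, bad-pixel repair, modulator drift correction,
Fourier integration of the two differential-phase channels, Butterworth
stripe suppression, parallel-beam filtered back-projection, and conversion
of the refractive-index decrement to electron density.

## Physical model

The specimen is described by its complex refractive index
`n = 1 - delta + i beta`. In the thin-object (projection) approximation a
ray accumulates

* a phase `Phi = -k * integral(delta dl)` and
* an intensity transmission `T = exp(-2 k * integral(beta dl))`,

with `k = 2 pi / lambda`. The virtual beamline propagates a plane wave
through the modulator screen (projected-thickness map converted to a
complex transmission), over the modulator-to-sample distance `z0`, through
the sample, and over the sample-to-detector distance `z`, using the
paraxial angular-spectrum propagator `exp(-i pi lambda z |f|^2)`. The
transfer function is unitary, so intensity is conserved exactly; a
sampling check rejects distances beyond `N dx^2 / lambda` where the
transfer-function phase would alias. Detector effects are a Gaussian PSF
(default FWHM 1.67 px, the equivalent of a 2.14 um system resolution at
1.28 um pixels), a mean photon count with Poisson statistics, and a dark
offset.

Defaults follow a typical synchrotron micro-CT arrangement: 20 keV
photons, 1.28 um effective pixels, `z0 = 115` mm, `z = 175` mm for MBI and
93 mm for PBI, a source so distant (85 m) that magnification is 1 and the
illumination is treated as a plane wave, with residual source blur folded
into the detector PSF.

A small built-in optical-constants layer supplies `delta` and `beta` for
the materials the simulator uses (silicon, silicon carbide, paraffin, soft
tissue, blood, water, air). `delta` is computed exactly from the electron
density via the classical-electron-radius relation; `beta` derives from a
compiled table of elemental mass attenuation coefficients at 20 keV with
`E^-3` photoelectric scaling, accurate to a few percent — sufficient
because no quantitative contract in the package depends on `beta`
precision. The 17 um silicon TAI etch yields a phase shift of
`r round(screen_phase_shift(make_tai_screen(shape_px = c(64, 64)), beam_config(20)), 4)`
rad at 20 keV, within 1% of the nominal 2*pi/3 design value.

## The synthetic phantom

`make_placenta_phantom()` emulates the morphology that matters for testing
the chain, not histological realism: a paraffin cylinder (radius 0.42 of
the field width, so the frame corners and lateral margins stay
sample-free), a straight "stem villus" of soft tissue running the full
height of the cylinder slightly off-centre (guaranteeing every axial slice
contains both tissue and paraffin, which the quantitative tests rely on),
randomly branching villous tubes with watery vessel lumina, and sparse
6 um "blood cell" spheres. Deterministic under a fixed seed.

What the phantom does **not** emulate: realistic villous packing density,
sub-resolution texture (so dark-field contrast is essentially absent),
fibrin deposits, container walls, beam-profile structure, vibration, or
polychromaticity. Passing end-to-end tests therefore demonstrates the
correctness of the algorithms under the stated forward model — not
performance on any particular beamline's data.

## Pattern matching

For each pixel `r` and candidate displacement `u`, the matcher minimises
the windowed, step-summed squared residual of the model

```
I_sam,m(r) ~ T * [ Ibar(r-u) + D * (I_ref,m(r-u) - Ibar(r-u)) ]
```

where `Ibar` is the reference mean over the modulator steps `m` and the
window is `(2h+1)^2` pixels (default `h = 1`, a 3x3 window). Because the
step-mean of `I_ref,m - Ibar` vanishes pointwise, the two regressors are
orthogonal and `T` and `D` have closed-form least-squares optima for every
candidate, so the discrete search is exact. The returned `u` is the
displacement of the sample pattern relative to the reference; with the
simulator's propagator convention, a phase gradient `dPhi/dx` displaces
the pattern by `+z (dPhi/dx) / k`, so `alpha = u * pixel / z_eff` and
`dPhi/dx = k alpha` hold with no sign ambiguity. `z_eff` defaults to the
sample-to-detector distance but is an explicit argument, since which
distance enters the proportionality depends on the geometry convention.

### Sub-pixel refinement

Three schemes are provided. `"refine_off"` returns the integer minimiser.
`"parabola"` adds separable 3-point parabola interpolation of the cost;
this classic estimator shows *pixel locking* — on the sharp TAI pattern it
under-reports displacements below ~0.3 px by roughly a third, which
collapses the scale of the integrated phase. The default `"iterative"`
therefore refines by iterative warping: the reference stack is warped by
the current displacement field (two-pass separable Lanczos-3 — short
kernels such as bilinear or Catmull-Rom deliver less than the nominal
shift at high spatial frequencies and bias the fixed point), re-matched
with radius 1 on mildly band-limited copies (Gaussian sigma 0.5 px, which
confines matching to the band where the interpolator is phase-accurate),
and the correction accumulated over 4 iterations, clamped to within 1 px
of the stage-one discrete minimum so the refinement can never migrate to a
different cost valley (important for periodic patterns and small step
counts). `T`, `D` and the residual are re-estimated on the unfiltered data
at the converged displacement. On simulated benchmarks this reduces the
displacement bias from ~35% (parabola) to under 5%.

The dark-field channel is retained but should be treated as qualitative:
at these propagation distances it is contaminated by edge fringes, and the
phantom contains no sub-resolution scatterers, so only the synthetic
blur-equivalence test binds it.

## Phase integration

The two differential channels are conditioned and integrated:

1. a first-order 2D polynomial fitted to background (sample-free) pixels
   is subtracted from each channel;
2. least-squares Fourier integration:
   `Phi_hat = -i (fx gx_hat + fy gy_hat) / (2 pi (fx^2 + fy^2))`, DC term
   zero (the absolute offset is unrecoverable from gradients). Before the
   transform the field is mirror-extended — even for the phase, hence
   odd/even for the gradients — to suppress wrap-around; for exactly
   periodic inputs `pad = FALSE` makes the oracle identity exact;
3. a second-order polynomial fitted to the background of the integrated
   phase is subtracted to remove residual low frequencies.

The default background mask is a frame border; for specimens that cross
the whole frame height (the usual tomographic column) `border_mask(...,
sides = "cols")` restricts it to the lateral margins — fitting on
top/bottom borders that lie inside the specimen shadow would subtract real
signal.

## Single-distance (Paganin) retrieval

The flat-corrected intensity ratio is filtered with
`1 / (1 + pi lambda z gamma |f|^2)` (`f` in cycles per metre, parallel
beam, magnification 1) and inverted through Beer-Lambert. The phase
channel `Phi = (gamma/2) ln(I_filtered)` needs only `gamma`; the projected
thickness additionally needs `delta` of the dominant material. The
configured default `gamma = 202.43` is a tabulated soft-tissue-in-wax
value; `tune_gamma()` computes the effective interface value
`(delta_a - delta_b) / (beta_a - beta_b)` from the package's own
constants, which for its soft-tissue/paraffin compositions gives
`r round(tune_gamma("soft_tissue", "paraffin", 20), 1)` — composition
models for "soft tissue" differ between tabulations, and the retrieval is
qualitative in any case, so the simulation arms use the self-consistent
`tune_gamma()` value.

## Tomography

Sinograms are conditioned with a stripe-suppression filter: the stripe
estimate (mean over angles per detector column) is Butterworth band-passed
along the column axis and subtracted from every projection. The module
defaults (`low_cut = 0.01`, `high_cut = 0.5` cycles/px, order 4) implement
a generic wide passband; the pipeline presets use `low_cut = 0.1` because
with a centred specimen the angle-mean contains the static object
envelope, and a 0.01 cutoff would subtract real signal, while the rings
this chain actually produces (static reference-frame noise imprinted on
every angle) are 1-2 px wide and live above 0.1 cycles/px. Filter
settings are per-dataset choices by design.

Reconstruction is a standard parallel-beam FBP with the band-limited ramp
kernel and linear-interpolation back-projection, scaled so that line
integrals of a quantity per metre reconstruct to that quantity per voxel
(a uniform disk reconstructs to its true `delta` within 0.1% at 181
angles). Differential-phase projections are integrated to `Phi` first and
`-Phi/k` is reconstructed to `delta`; direct Hilbert-filtered DPC
reconstruction is not implemented. Electron density follows
`rho_e = delta k^2 / (2 pi r0)` (reported per cubic angstrom) and
attenuation `mu = 2 k beta`; both are exact linear maps.

## Image-quality metrics

* **Visibility**: sliding-window standard deviation over mean (population
  variance; window default 15 px, covering at least two TAI periods).
* **Speckle / marking-structure size**: FWHM of the central peak of the
  mean-subtracted autocorrelation, both axes averaged, sub-pixel by linear
  interpolation of the half-maximum crossings.
* **Fourier-spectrum resolution**: azimuthally averaged power spectrum
  compared against a flat noise floor predicted from a homogeneous ROI via
  Parseval (`floor = N sigma^2`); the crossing is located in the log
  domain with a 20% tolerance band that absorbs the sampling error of the
  ROI floor estimate; if the spectrum starts at the floor the
  Nyquist-limited bound is returned and flagged.
* **Angular sensitivity**: standard deviation of the refraction-angle maps
  over a sample-free ROI (nrad).
* **Phase sensitivity**: standard deviation of electron density over a
  homogeneous ROI (electrons/A^3).
* **CNR**: `|I_s - I_b| / sigma_b` between disjoint signal and background
  ROIs (conventionally 40x40 px).

## The three-arm experiment

`run_experiment()` simulates MBI-with-TAI, MBI-with-sandpaper and PBI
scans of the same phantom and seed, reconstructs aligned central slices,
and assembles one metrics row per arm. Problem sizes are configuration
presets: `"smoke"` (64^2 detector, 45 angles, 4/6 steps) exercises every
stage in seconds; `"benchmark"` (128^2 detector, 181 angles over 180
degrees, 16-step tilted grid for the TAI and 20-step spiral for the
sandpaper, 10^4 photons/px) is the standard quantitative setting used by
the package's own validation; `"paper_scale"` mirrors a full synchrotron
acquisition (5120 x 2151 detector, 3001 angles) for configuration
inspection. Step counts follow the acquisition convention that the tilted
grid scans exactly one TAI unit cell and the spiral gives pairwise
distinct diffuser positions.

ROIs are derived from the ground-truth labels: a tissue ROI inside the
stem villus, a paraffin ROI for the homogeneous-noise figures, and an
air-corner ROI for angular sensitivity. On the benchmark preset the TAI
arm recovers the tissue-paraffin `delta` contrast to within 10% and the
absolute paraffin `delta` to within a few percent; the sandpaper arm,
whose marking structures are coarser than the TAI's (autocorrelation FWHM
~3.1 px vs ~2.2 px), shows several-fold higher electron-density noise —
the finer marker gives the better phase sensitivity, matching the
qualitative expectation for these two wavefront markers.

## Numerical choices and degenerate inputs

* Windowed sums truncate at frame borders; all cost terms share the same
  truncation so the least-squares optima remain valid there, but the
  outermost `search_radius` pixels see circularly wrapped references and
  should not be quantitatively trusted.
* Windows with zero reference modulation make `D` unidentifiable; they are
  counted, `D` is fixed to 1, and `T` falls back to the mean-regressor
  estimate.
* Bad pixels: 8-connected neighbour lower-median (ties resolve to the
  smaller value), detection against a robust MAD-scaled threshold;
  repairing twice changes nothing.
* Drift registration uses phase correlation with a matrix-DFT sub-pixel
  refinement; on periodic (TAI) patterns the correlation peak is ambiguous
  beyond half a lattice period, which is why diffusers are the standard
  drift reference.
* The Paganin filter clips non-positive filtered intensities (counted and
  warned) before the logarithm.
* All stochastic stages draw from R's RNG seeded per scan/arm, so a
  configuration plus seed reproduces a dataset bit for bit.

## Known limitations

Thin-object projection approximation for both modulator and specimen (no
multi-slice propagation); plane-wave illumination (no cone-beam
magnification, no partial-coherence model beyond the PSF);
monochromatic beam; rigid modulator drift only; the dark-field channel is
qualitative; PBI quantitativeness is limited to specimens matching the
single configured `gamma`.
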