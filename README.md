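# xpci

Simulation and quantitative analysis of **X-ray phase-contrast
micro-tomography** with wavefront modulators, in R.

For weakly absorbing specimens — the motivating case is paraffin-embedded
soft tissue imaged at a synchrotron micro-CT beamline — conventional
attenuation contrast is poor, but the phase of the transmitted wavefront
carries strong contrast through the refractive index decrement δ of
`n = 1 − δ + iβ`. `xpci` implements two complementary retrieval routes and
everything needed to compare them quantitatively:

* **Modulation-based imaging (MBI).** A wavefront marker — a hexagonal
  Talbot array illuminator (TAI) phase grating or stacked sandpaper
  diffuser — imprints a reference intensity pattern on the beam and is
  stepped transversely. A windowed least-squares pattern match (UMPA-style)
  recovers per pixel the transmission `T`, the pattern displacement
  `(u_x, u_y)` and the dark-field `D`. Displacements convert to refraction
  angles `α = u·p/z_eff` and differential phase `∂Φ/∂x = k·α`; Fourier
  (least-squares) integration with polynomial background detrending yields
  the absolute phase `Φ = −k∫δ dl`.
* **Propagation-based imaging (PBI).** Free-space propagation alone turns
  phase gradients into edge fringes, inverted with the single-distance
  Paganin filter `1/(1 + πλzγ|f|²)`, `γ = δ/β`.

Both routes feed a parallel-beam filtered back-projection (after
Butterworth stripe suppression of ring artifacts), and δ converts to
electron density via `ρe = δk²/(2πr0)`. An image-quality suite implements
the standard figures: pattern visibility, autocorrelation speckle size,
Fourier-spectrum spatial resolution, angular sensitivity (σ_α), phase
sensitivity (σ_ρe) and contrast-to-noise ratio.

Because real datasets of this kind are rarely public, the package includes
a **wave-optics virtual beamline** (`simulate_scan()`, `run_experiment()`):
thin-object phantoms with ground truth, TAI/sandpaper screens, angular-
spectrum Fresnel propagation, detector PSF and Poisson noise — so the whole
chain is testable end to end with known answers.

## Worked example

A complete three-arm comparison (MBI with TAI, MBI with sandpaper, PBI) on
the built-in placenta-like phantom:

```r
library(xpci)

cfg <- preset_config("smoke", seed = 1)   # 64^2 detector, 45 angles: seconds
ex  <- run_experiment(cfg)
ex$report[, c("method", "mean_visibility", "autocorr_fwhm_px",
              "sigma_rho_e", "cnr_mean")]
#>          method mean_visibility autocorr_fwhm_px sigma_rho_e cnr_mean
#> 1       mbi_tai           0.718             2.22     0.01246     4.52
#> 2 mbi_sandpaper           0.599             3.05     0.06630     1.33
#> 3           pbi              NA               NA     0.00673     5.77
```

Reading the report: the TAI produces a finer reference pattern than the
sandpaper (autocorrelation FWHM 2.22 px vs 3.05 px), and correspondingly
the TAI arm reaches a several-fold better phase sensitivity (σ_ρe, in
electrons/Å³) — the finer the marking structure, the smaller the electron-
density difference the reconstruction can resolve. The `smoke` preset is a
fast qualitative exercise; quantitative accuracy statements (e.g. the
tissue-vs-paraffin δ contrast recovered within 10%) are made on the
`benchmark` preset (128³ phantom, 181 angles, 16/20 modulator steps),
which is what the acceptance script below runs.

Single components are just as accessible:

```r
b <- beam_config(20)                       # 20 keV
s <- make_tai_screen(period_um = 7, duty_cycle = 1/3, etch_depth_um = 17)
screen_phase_shift(s, b)                   # 2.077 rad, i.e. ~2*pi/3
px_to_um(5.82, pixel_um = 1.28)            # 7.4496 um speckle size
tune_gamma("soft_tissue", "paraffin", 20)  # Paganin gamma for the interface
```

## Package layout

| module | contents |
|---|---|
| `R/beam.R`, `R/materials.R` | beam/geometry/detector configs, unit layer, tabulated optical constants |
| `R/modulator.R`, `R/phantom.R`, `R/propagate.R`, `R/simulate.R` | virtual beamline: screens, stepping patterns, phantoms, Fresnel propagation, scan simulation |
| `R/preprocess.R` | dark/flat, bad pixels, beam profile, drift correction |
| `R/umpa.R` | windowed pattern matching, displacement → angle → DPC |
| `R/integrate.R` | DPC detrending, Fourier integration, phase detrending |
| `R/paganin.R` | single-distance phase retrieval, γ selection |
| `R/tomo.R` | ring filter, FBP, electron density / attenuation conversion |
| `R/metrics.R` | visibility, speckle FWHM, resolution, sensitivities, CNR |
| `R/pipeline.R`, `R/io.R` | presets, three-arm experiment, TIFF scan layout |

The methods vignette (`vignettes/methods.Rmd`) documents the forward
model, the matching cost and its sub-pixel refinement, all tunable
parameters with their defaults, and the package's design decisions and
limitations.
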