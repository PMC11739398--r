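# Beam configuration, physical constants and the pixel/micron unit layer.

#' Physical constants used throughout the package
#'
#' @format A list with elements:
#' \describe{
#'   \item{hc_eV_m}{Planck constant times speed of light, in eV m.}
#'   \item{r0_m}{classical electron radius, in m.}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#' }
#' @export
physical_constants <- list(
  hc_eV_m = 1.23984193e-6,
  r0_m    = 2.8179403262e-15,
  N_A     = 6.02214076e23
)

#' Monochromatic beam configuration
#'
#' Derives wavelength and wavenumber from the photon energy. The default
#' energy is 20 keV, a typical choice for micro-CT of paraffin-embedded soft
#' tissue.
#'
#' @param energy_keV photon energy in keV (> 0).
#' @return An object of class `beam_config` with fields `energy_keV`,
#'   `wavelength_m` (lambda = hc/E) and `wavenumber` (k = 2*pi/lambda, 1/m).
#' @examples
#' b <- beam_config(20)
#' b$wavelength_m          # ~6.199e-11 m
#' b$wavenumber * b$wavelength_m / (2 * pi)  # exactly 1
#' @export
beam_config <- function(energy_keV = 20) {
  check_that(is.numeric(energy_keV) && length(energy_keV) == 1 && energy_keV > 0,
             "energy_keV must be a positive scalar")
  lambda <- physical_constants$hc_eV_m / (energy_keV * 1e3)
  structure(list(
    energy_keV   = energy_keV,
    wavelength_m = lambda,
    wavenumber   = 2 * pi / lambda
  ), class = "beam_config")
}

#' @export
print.beam_config <- function(x, ...) {
  cat(sprintf("<beam_config> E = %g keV, lambda = %.4g m, k = %.4g 1/m\n",
              x$energy_keV, x$wavelength_m, x$wavenumber))
  invisible(x)
}

#' Convert between detector pixels and microns
#'
#' The unit layer used for all printed pixel/micron conversions (field of
#' view, speckle size, resolution figures).
#'
#' @param px lengths in pixels.
#' @param um lengths in microns.
#' @param pixel_um effective pixel pitch in the sample plane (microns/pixel).
#' @return `px_to_um()` returns microns; `um_to_px()` returns pixels.
#' @examples
#' px_to_um(5.82, 1.28)  # 7.4496 um
#' um_to_px(2.14, 1.28)  # 1.671875 px
#' @export
px_to_um <- function(px, pixel_um) {
  check_that(all(pixel_um > 0), "pixel_um must be > 0")
  px * pixel_um
}

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_um) {
  check_that(all(pixel_um > 0), "pixel_um must be > 0")
  um / pixel_um
}

#' Scan geometry
#'
#' Distances of the standard modulation-based (MBI) / propagation-based (PBI)
#' setup: modulator at `z0_m` upstream of the sample, detector at `z_prop_m`
#' downstream, source at `source_dist_m` (large enough that magnification is
#' ~1 and the beam is treated as a plane wave).
#'
#' @param z_prop_m sample-to-detector propagation distance (m). Defaults to
#'   the MBI distance 0.175 m; use 0.093 m for PBI.
#' @param z0_m modulator-to-sample distance (m).
#' @param source_dist_m source-to-detector distance (m).
#' @param n_angles number of projections over the angular range.
#' @param angular_range_deg angular coverage of the scan (180 for parallel
#'   beam).
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(z_prop_m = 0.175, z0_m = 0.115, source_dist_m = 85,
                          n_angles = 3001, angular_range_deg = 180) {
  check_that(z_prop_m > 0 && z0_m > 0 && source_dist_m > 0,
             "all distances must be > 0")
  check_that(n_angles >= 1, "n_angles must be >= 1")
  structure(list(z_prop_m = z_prop_m, z0_m = z0_m,
                 source_dist_m = source_dist_m, n_angles = as.integer(n_angles),
                 angular_range_deg = angular_range_deg),
            class = "scan_geometry")
}

#' Detector model
#'
#' Gaussian point-spread function plus Poisson photon statistics. The default
#' PSF FWHM of 1.67 px corresponds to a 2.14 micron system resolution at the
#' default 1.28 micron pixel pitch.
#'
#' @param pixel_um effective pixel pitch in the sample plane (microns).
#' @param shape_px integer vector `c(rows, cols)`.
#' @param psf_fwhm_px Gaussian PSF full width at half maximum, in pixels
#'   (0 disables blurring).
#' @param photons_per_px mean photon count per pixel in the open beam;
#'   `Inf` disables photon noise.
#' @param dark_level mean dark-current counts per pixel.
#' @param n_dark,n_flat number of dark / reference frames acquired per scan.
#' @return object of class `detector_model`.
#' @export
detector_model <- function(pixel_um = 1.28, shape_px = c(256, 256),
                           psf_fwhm_px = 1.67, photons_per_px = 1e4,
                           dark_level = 0, n_dark = 20, n_flat = 70) {
  check_that(pixel_um > 0, "pixel_um must be > 0")
  check_that(psf_fwhm_px >= 0, "psf_fwhm_px must be >= 0")
  check_that(all(shape_px >= 8), "detector must be at least 8x8 px")
  structure(list(pixel_um = pixel_um, shape_px = as.integer(shape_px),
                 psf_fwhm_px = psf_fwhm_px, photons_per_px = photons_per_px,
                 dark_level = dark_level, n_dark = as.integer(n_dark),
                 n_flat = as.integer(n_flat)),
            class = "detector_model")
}
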