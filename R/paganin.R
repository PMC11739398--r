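# Single-distance propagation-based phase retrieval: the Paganin-type
# low-pass filter applied to flat-corrected intensity ratios, plus the
# material-ratio helper for choosing the filter parameter.

#' Paganin filter configuration
#'
#' @param gamma delta/beta ratio of the dominant material pair (the
#'   default 202.43 is a tabulated soft-tissue-in-wax value).
#' @param z_m propagation distance in m (default 0.093).
#' @param energy_keV photon energy.
#' @param pixel_um detector pixel pitch (microns).
#' @param delta optional refractive index decrement of the dominant
#'   material, used to report projected thickness and phase on absolute
#'   scales; when `NULL` only the phase channel (which needs only gamma) is
#'   returned.
#' @return object of class `paganin_config`.
#' @export
paganin_config <- function(gamma = 202.43, z_m = 0.093, energy_keV = 20,
                           pixel_um = 1.28, delta = NULL) {
  check_that(gamma > 0, "gamma must be > 0")
  check_that(z_m > 0, "z_m must be > 0")
  structure(list(gamma = gamma, z_m = z_m, energy_keV = energy_keV,
                 pixel_um = pixel_um, delta = delta),
            class = "paganin_config")
}

#' Single-distance (Paganin) phase retrieval
#'
#' Applies the low-pass transfer function `1 / (1 + pi lambda z gamma |f|^2)`
#' (f in cycles per metre) to the flat-corrected intensity ratio and inverts
#' Beer-Lambert. The phase channel is
#' `Phi = (gamma / 2) * ln(I_filtered)`, equal to `-k delta t` for a
#' homogeneous object of the configured material; when `delta` is supplied
#' in the config the projected thickness `t = -Phi / (k delta)` is returned
#' as well.
#'
#' @param intensity_ratio_image flat-corrected image `I_z / I_0`, strictly
#'   positive.
#' @param config a [paganin_config()].
#' @param pad `"mirror"` (default; even extension before the FFT to avoid
#'   wrap-around) or `"none"` (periodic input).
#' @return a [phase_projection()]; attributes `thickness_m` (when `delta`
#'   is available) and `n_clipped` (pixels clipped to positive before the
#'   logarithm).
#' @export
paganin_filter <- function(intensity_ratio_image, config = paganin_config(),
                           pad = c("mirror", "none")) {
  pad <- match.arg(pad)
  I <- intensity_ratio_image
  check_that(all(I > 0), "intensity ratio must be strictly positive")
  lambda <- physical_constants$hc_eV_m / (config$energy_keV * 1e3)
  k <- 2 * pi / lambda
  d_m <- config$pixel_um * 1e-6
  nr0 <- nrow(I); nc0 <- ncol(I)
  if (pad == "mirror") I <- mirror_pad_even(I)
  fy <- fft_freq(nrow(I), d_m); fx <- fft_freq(ncol(I), d_m)
  H <- 1 / (1 + pi * lambda * config$z_m * config$gamma *
              outer(fy^2, fx^2, `+`))
  If <- Re(ifft2(fft2(I) * H))
  if (pad == "mirror") If <- If[seq_len(nr0), seq_len(nc0)]
  n_clipped <- sum(If <= 0)
  if (n_clipped > 0) {
    warning(sprintf("%d non-positive pixels after filtering were clipped",
                    n_clipped))
    If[If <= 0] <- min(If[If > 0])
  }
  phi <- (config$gamma / 2) * log(If)
  out <- phase_projection(phi, config$pixel_um)
  if (!is.null(config$delta)) {
    mu <- 4 * pi * (config$delta / config$gamma) / lambda
    attr(out, "thickness_m") <- -log(If) / mu
  }
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Phase-retrieval parameter from tabulated optical constants
#'
#' Effective `gamma = delta_eff / beta_eff` for a two-material interface:
#' `(delta_a - delta_b) / (beta_a - beta_b)` from the package's tabulated
#' optical constants at the beam energy. With identical materials the
#' material's own `delta / beta` is returned.
#'
#' @param material_a,material_b material names or custom constants (see
#'   [optical_constants()]).
#' @param energy_keV photon energy.
#' @return gamma (dimensionless scalar).
#' @export
tune_gamma <- function(material_a, material_b, energy_keV = 20) {
  a <- optical_constants(material_a, energy_keV)
  b <- optical_constants(material_b, energy_keV)
  same <- identical(a$material_name, b$material_name) ||
    (a$delta == b$delta && a$beta == b$beta)
  if (same) {
    if (a$beta <= 0) stop("pure-phase material: beta is zero, gamma diverges")
    return(a$delta / a$beta)
  }
  dbeta <- a$beta - b$beta
  if (abs(dbeta) < .Machine$double.xmin * 1e10 || dbeta == 0)
    stop("materials have equal beta: effective gamma diverges")
  (a$delta - b$delta) / dbeta
}
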