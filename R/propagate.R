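# Free-space propagation of a complex scalar field by the angular-spectrum
# (Fresnel transfer function) method.

#' Fresnel free-space propagation
#'
#' Propagates a sampled complex field by multiplying its angular spectrum
#' with the paraxial transfer function `exp(-i pi lambda z (fx^2 + fy^2))`.
#' The transfer function is unitary, so total intensity is conserved to
#' numerical precision. Sampling is checked: the transfer-function phase must
#' be unaliased at the maximum frequency, which requires
#' `z <= N * pixel^2 / lambda`.
#'
#' @param field complex matrix (the wavefront).
#' @param distance_m propagation distance in m (0 returns the field
#'   unchanged; negative propagates backwards).
#' @param beam a [beam_config()].
#' @param pixel_um transverse sampling pitch in microns.
#' @return complex matrix of the same size.
#' @export
fresnel_propagate <- function(field, distance_m, beam, pixel_um) {
  if (distance_m == 0) return(field)
  lambda <- beam$wavelength_m
  dx <- pixel_um * 1e-6
  n_min <- min(dim(field))
  z_max <- n_min * dx^2 / lambda
  if (abs(distance_m) > z_max)
    stop(sprintf(paste0("propagation distance %.3g m aliases the transfer ",
                        "function (limit %.3g m for this grid); pad the field ",
                        "or use a coarser distance/finer sampling"),
                 distance_m, z_max))
  fy <- fft_freq(nrow(field), dx)
  fx <- fft_freq(ncol(field), dx)
  H <- exp(-1i * pi * lambda * distance_m * outer(fy^2, fx^2, `+`))
  ifft2(fft2(field) * H)
}

#' Thin-object transmission function
#'
#' `exp(-k beta t) * exp(-i k delta t)` for projected thickness maps in m.
#'
#' @param delta_t_map,beta_t_map line integrals of delta and beta (m).
#' @param beam a [beam_config()].
#' @return complex transmission matrix.
#' @keywords internal
object_transmission <- function(delta_t_map, beta_t_map, beam) {
  k <- beam$wavenumber
  out <- exp(complex(real = -k * beta_t_map, imaginary = -k * delta_t_map))
  matrix(out, nrow(delta_t_map), ncol(delta_t_map))
}
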