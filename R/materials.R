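# Tabulated X-ray optical constants for the handful of materials the
# simulator uses.
#
# delta (refractive index decrement) is computed exactly from the material
# composition via the classical relation
#     delta = r0 * lambda^2 * n_e / (2 pi),
# valid far from absorption edges (all materials here have edges well below
# 10 keV). beta is derived from a compiled table of elemental mass
# attenuation coefficients at 20 keV; away from 20 keV the photoelectric part
# is scaled as E^-3 with the incoherent part held constant, which is adequate
# at the few-percent level over 15-40 keV for these light materials.

# Elemental data: Z, molar mass A (g/mol), mass attenuation coefficient at
# 20 keV (cm^2/g, total minus coherent; standard compilation values,
# approximate to a few percent), and the incoherent (Compton) part at 20 keV.
.element_data <- data.frame(
  symbol   = c("H",     "C",      "N",      "O",      "Si"),
  Z        = c(1,       6,        7,        8,        14),
  A        = c(1.008,   12.011,   14.007,   15.999,   28.0855),
  mu_rho20 = c(0.3695,  0.4420,   0.6180,   0.8651,   4.464),
  mu_rho20_incoh = c(0.370, 0.1861, 0.1862, 0.1863, 0.1857),
  stringsAsFactors = FALSE
)

# Built-in materials: density (g/cm^3) and elemental mass fractions.
.material_data <- list(
  silicon         = list(density = 2.33, fractions = c(Si = 1)),
  silicon_carbide = list(density = 3.21,
                         fractions = c(Si = 28.0855 / 40.096, C = 12.011 / 40.096)),
  paraffin        = list(density = 0.90,  # C25H52
                         fractions = c(C = 300.275 / 352.691, H = 52.416 / 352.691)),
  soft_tissue     = list(density = 1.06,
                         fractions = c(H = 0.102, C = 0.143, N = 0.034, O = 0.721)),
  blood           = list(density = 1.06,
                         fractions = c(H = 0.102, C = 0.110, N = 0.033, O = 0.755)),
  water           = list(density = 1.00,
                         fractions = c(H = 2 * 1.008 / 18.015, O = 15.999 / 18.015)),
  air             = list(density = 1.205e-3,
                         fractions = c(N = 0.755, O = 0.245))
)

#' Names of the built-in materials
#' @return character vector of material names accepted by
#'   [optical_constants()].
#' @export
material_names <- function() names(.material_data)

#' Optical constants of a built-in material
#'
#' Returns the complex refractive index components `n = 1 - delta + i beta`
#' for one of the built-in materials at the given photon energy. `delta` is
#' computed exactly from the electron density; `beta` comes from tabulated
#' 20 keV mass attenuation coefficients with photoelectric `E^-3` scaling.
#'
#' @param material material name (see [material_names()]), or a list with
#'   fields `material_name`, `delta`, `beta` which is returned unchanged
#'   (allowing user-supplied constants anywhere a material is accepted).
#' @param energy_keV photon energy in keV.
#' @return object of class `optical_constants`: list with `material_name`,
#'   `delta`, `beta`.
#' @examples
#' si <- optical_constants("silicon", 20)
#' si$delta        # ~1.21e-6
#' @export
optical_constants <- function(material, energy_keV = 20) {
  if (is.list(material)) {
    check_that(all(c("material_name", "delta", "beta") %in% names(material)),
               "custom material needs material_name, delta, beta")
    check_that(material$delta >= 0 && material$beta >= 0,
               "delta and beta must be >= 0")
    return(structure(material[c("material_name", "delta", "beta")],
                     class = "optical_constants"))
  }
  m <- .material_data[[material]]
  if (is.null(m)) stop("unknown material: ", material,
                       " (known: ", paste(material_names(), collapse = ", "), ")")
  el <- .element_data[match(names(m$fractions), .element_data$symbol), ]
  lambda <- physical_constants$hc_eV_m / (energy_keV * 1e3)
  # electron density (1/m^3): rho [g/m^3] * N_A * sum(w_i Z_i / A_i)
  ne <- m$density * 1e6 * physical_constants$N_A *
    sum(m$fractions * el$Z / el$A)
  delta <- physical_constants$r0_m * lambda^2 * ne / (2 * pi)
  # mass attenuation at energy: photoelectric scaled E^-3, incoherent constant
  scale <- (20 / energy_keV)^3
  mu_rho <- sum(m$fractions *
                  ((el$mu_rho20 - el$mu_rho20_incoh) * scale + el$mu_rho20_incoh))
  mu_m <- mu_rho * m$density * 100  # cm^2/g * g/cm^3 = 1/cm -> 1/m
  beta <- mu_m * lambda / (4 * pi)
  structure(list(material_name = material, delta = delta, beta = beta),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> %s: delta = %.4g, beta = %.4g\n",
              x$material_name, x$delta, x$beta))
  invisible(x)
}
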