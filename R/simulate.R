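# Virtual beamline: single-frame forward model and full scan simulation.

# Sample a (possibly larger) screen thickness map on the detector grid with a
# transverse offset, bilinear interpolation, replicated edges. Positive
# offset moves the pattern content by +offset on the detector.
screen_window <- function(screen, shape_px, offset_px = c(0, 0)) {
  tm <- screen$thickness_map_um
  nr <- shape_px[1]; nc <- shape_px[2]
  my <- (nrow(tm) - nr) / 2; mx <- (ncol(tm) - nc) / 2
  y <- pmin(pmax(seq_len(nr) + my - offset_px[1], 1), nrow(tm))
  x <- pmin(pmax(seq_len(nc) + mx - offset_px[2], 1), ncol(tm))
  y0 <- pmin(floor(y), nrow(tm) - 1); x0 <- pmin(floor(x), ncol(tm) - 1)
  wy <- y - y0; wx <- x - x0
  a <- tm[y0, x0, drop = FALSE]; b <- tm[y0, x0 + 1, drop = FALSE]
  c_ <- tm[y0 + 1, x0, drop = FALSE]; d <- tm[y0 + 1, x0 + 1, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

# complex field of the screen at its own plane, on the detector grid
screen_field <- function(screen, shape_px, offset_px, beam) {
  t_um <- screen_window(screen, shape_px, offset_px)
  oc <- optical_constants(screen$material, beam$energy_keV)
  object_transmission(oc$delta * t_um * 1e-6, oc$beta * t_um * 1e-6, beam)
}

#' Simulate one detector frame
#'
#' Forward model: plane wave, times the modulator screen transmission
#' (shifted by `screen_offset_px`), propagated over the modulator-to-sample
#' distance, times the thin-object sample transmission, propagated over the
#' sample-to-detector distance; the intensity is blurred by the detector PSF,
#' scaled to photons, and Poisson noise plus dark counts are added.
#'
#' With `screen = NULL` and a phantom this is a propagation-based (PBI)
#' frame; with `phantom = NULL` a reference frame; with both absent a flat
#' frame.
#'
#' @param geometry a [scan_geometry()].
#' @param beam a [beam_config()].
#' @param detector a [detector_model()].
#' @param screen a [modulator_screen()] or `NULL`.
#' @param screen_offset_px transverse modulator offset `c(dy, dx)` in px.
#' @param phantom a [phantom()] or `NULL`.
#' @param angle_deg tomographic rotation angle.
#' @param seed optional RNG seed for the photon noise of this frame.
#' @param noise logical; `FALSE` returns the noise-free expectation.
#' @param projection optional precomputed [project_phantom()] output for this
#'   angle (avoids recomputation across modulator steps).
#' @param sample_plane_field optional precomputed screen field already
#'   propagated to the sample plane.
#' @return numeric matrix of detector counts.
#' @export
simulate_frame <- function(geometry, beam, detector, screen = NULL,
                           screen_offset_px = c(0, 0), phantom = NULL,
                           angle_deg = 0, seed = NULL, noise = TRUE,
                           projection = NULL, sample_plane_field = NULL) {
  shp <- detector$shape_px
  if (!is.null(sample_plane_field)) {
    U <- sample_plane_field
    check_that(all(dim(U) == shp), "sample_plane_field/detector shape mismatch")
  } else if (!is.null(screen)) {
    U <- screen_field(screen, shp, screen_offset_px, beam)
    U <- fresnel_propagate(U, geometry$z0_m, beam, detector$pixel_um)
  } else {
    U <- matrix(1 + 0i, shp[1], shp[2])
  }
  if (!is.null(phantom)) {
    pr <- projection %||% project_phantom(phantom, angle_deg)
    check_that(all(dim(pr$delta_t_map) == shp),
               "phantom projection does not match the detector grid")
    U <- U * object_transmission(pr$delta_t_map, pr$beta_t_map, beam)
  }
  U <- fresnel_propagate(U, geometry$z_prop_m, beam, detector$pixel_um)
  I <- Re(U * Conj(U))
  if (detector$psf_fwhm_px > 0)
    I <- gauss_blur(I, detector$psf_fwhm_px / (2 * sqrt(2 * log(2))))
  I <- I * detector$photons_per_px
  if (noise) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    I <- matrix(stats::rpois(length(I), I), nrow(I), ncol(I))
    if (detector$dark_level > 0)
      I <- I + matrix(stats::rpois(length(I), detector$dark_level),
                      nrow(I), ncol(I))
  } else {
    I <- I + detector$dark_level
  }
  I
}

#' Scan configuration for the simulator
#'
#' @param beam,geometry,detector component configurations.
#' @param phantom a [phantom()] or `NULL`.
#' @param screen a [modulator_screen()] or `NULL` (PBI).
#' @param stepping a [stepping_pattern()] or `NULL` for a single static
#'   position.
#' @param n_angles number of projections over 180 degrees.
#' @param n_ref reference frames per modulator step.
#' @param noise logical; Poisson noise on/off.
#' @param drift_px total linear modulator drift `c(dy, dx)` in px across the
#'   scan (0 = no drift).
#' @param seed RNG seed for the whole scan.
#' @return object of class `scan_config`.
#' @export
scan_config <- function(beam = beam_config(), geometry = scan_geometry(),
                        detector = detector_model(), phantom = NULL,
                        screen = NULL, stepping = NULL, n_angles = 1,
                        n_ref = 5, noise = TRUE, drift_px = c(0, 0), seed = 1) {
  structure(list(beam = beam, geometry = geometry, detector = detector,
                 phantom = phantom, screen = screen, stepping = stepping,
                 n_angles = as.integer(n_angles), n_ref = as.integer(n_ref),
                 noise = noise, drift_px = drift_px, seed = seed),
            class = "scan_config")
}

#' Simulate a complete scan
#'
#' Emits dark frames, per-step reference frames, per-step/per-angle sample
#' frames and the ground truth (the phantom plus the true phase map per
#' angle, `Phi = -k * integral(delta)`). Optional linear modulator drift is
#' injected across the tomographic angles.
#'
#' @param config a [scan_config()].
#' @param out_dir optional directory; when given, the dataset is also
#'   written in the on-disk layout of [write_scan_dir()].
#' @return list with elements `dark` (array `[n_dark, rows, cols]`),
#'   `reference` (array `[step, rep, rows, cols]`), `sample` (array
#'   `[step, angle, rows, cols]`), `angles_deg`, `ground_truth` (list with
#'   `phantom`, `phi` list per angle, `transmission` list per angle) and the
#'   `config`.
#' @export
simulate_scan <- function(config, out_dir = NULL) {
  cfg <- config
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  det <- cfg$detector; shp <- det$shape_px
  offs <- if (!is.null(cfg$stepping)) cfg$stepping$offsets_px
          else matrix(0, 1, 2)
  n_step <- nrow(offs)
  est_gb <- 8 * prod(shp) *
    (n_step * (cfg$n_angles + cfg$n_ref) + det$n_dark) / 2^30
  if (est_gb > 4)
    warning(sprintf("dataset estimate %.1f GiB; consider a smaller preset",
                    est_gb))
  angles <- seq(0, cfg$geometry$angular_range_deg,
                length.out = cfg$n_angles + 1)[seq_len(cfg$n_angles)]

  dark <- array(0, c(det$n_dark, shp))
  for (i in seq_len(det$n_dark))
    dark[i, , ] <- if (cfg$noise && det$dark_level > 0)
      matrix(stats::rpois(prod(shp), det$dark_level), shp[1], shp[2])
    else matrix(det$dark_level, shp[1], shp[2])

  # screen fields at the sample plane, one per step (reused for all angles)
  fields <- NULL
  if (!is.null(cfg$screen)) {
    fields <- vector("list", n_step)
    for (s in seq_len(n_step)) {
      U <- screen_field(cfg$screen, shp, offs[s, ], cfg$beam)
      fields[[s]] <- fresnel_propagate(U, cfg$geometry$z0_m, cfg$beam,
                                       det$pixel_um)
    }
  }

  reference <- array(0, c(n_step, cfg$n_ref, shp))
  for (s in seq_len(n_step)) for (r in seq_len(cfg$n_ref))
    reference[s, r, , ] <- simulate_frame(
      cfg$geometry, cfg$beam, det, screen = cfg$screen,
      screen_offset_px = offs[s, ], noise = cfg$noise,
      sample_plane_field = if (!is.null(fields)) fields[[s]])

  sample <- array(0, c(n_step, cfg$n_angles, shp))
  phi_true <- vector("list", cfg$n_angles)
  trans_true <- vector("list", cfg$n_angles)
  for (j in seq_len(cfg$n_angles)) {
    pr <- if (!is.null(cfg$phantom))
      project_phantom(cfg$phantom, angles[j]) else NULL
    if (!is.null(pr)) {
      phi_true[[j]] <- -cfg$beam$wavenumber * pr$delta_t_map
      trans_true[[j]] <- exp(-2 * cfg$beam$wavenumber * pr$beta_t_map)
    }
    dr <- if (cfg$n_angles > 1) (j - 1) / (cfg$n_angles - 1) else 0
    drift <- cfg$drift_px * dr
    for (s in seq_len(n_step)) {
      fld <- if (!is.null(fields)) {
        if (any(drift != 0))
          fresnel_propagate(
            screen_field(cfg$screen, shp, offs[s, ] + drift, cfg$beam),
            cfg$geometry$z0_m, cfg$beam, det$pixel_um)
        else fields[[s]]
      } else NULL
      sample[s, j, , ] <- simulate_frame(
        cfg$geometry, cfg$beam, det, screen = cfg$screen,
        phantom = cfg$phantom, angle_deg = angles[j], noise = cfg$noise,
        projection = pr, sample_plane_field = fld)
    }
  }

  out <- list(dark = dark, reference = reference, sample = sample,
              angles_deg = angles,
              ground_truth = list(phantom = cfg$phantom, phi = phi_true,
                                  transmission = trans_true),
              config = cfg)
  if (!is.null(out_dir)) write_scan_dir(out, out_dir)
  out
}
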