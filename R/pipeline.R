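# Orchestration: configuration presets and the three-arm experiment
# (MBI with TAI, MBI with sandpaper, PBI) on a common phantom.

#' Pipeline configuration presets
#'
#' Bundles every stage configuration for a full simulated experiment.
#' `"smoke"` (64^2 detector, 45 angles, 4/6 modulator steps) runs in
#' seconds; `"benchmark"` (128^2 detector, 181 angles, 16/20 steps) is the
#' standard quantitative preset; `"paper_scale"` mirrors a full synchrotron
#' acquisition (3001 angles, 5120 x 2151 detector) and is intended for
#' configuration inspection, not desk-scale execution.
#'
#' @param preset preset name.
#' @param seed RNG seed used for the phantom, screens and photon noise.
#' @return object of class `pipeline_config` (a named list of stage
#'   configurations).
#' @export
preset_config <- function(preset = c("smoke", "benchmark", "paper_scale"),
                          seed = 1) {
  preset <- match.arg(preset)
  beam <- beam_config(20)
  base <- list(
    preset = preset, seed = seed, beam = beam,
    geometry_mbi = scan_geometry(z_prop_m = 0.175),
    geometry_pbi = scan_geometry(z_prop_m = 0.093),
    tai = list(period_um = 7, duty_cycle = 1 / 3, etch_depth_um = 17,
               material = "silicon"),
    sandpaper = list(grain_mean_um = 5.8, n_layers = 6,
                     material = "silicon_carbide"),
    match = match_config(window_half_px = 1, search_radius_px = 2),
    # stripe passband for ring suppression: rings from static reference
    # noise are 1-2 px wide (f > ~0.1 cycles/px); a higher low cut spares
    # the smooth envelope of the centred specimen
    ring = list(low_cut = 0.1, high_cut = 0.5, order = 4),
    border_px = 6, noise = TRUE, drift_px = c(0, 0)
  )
  dims <- switch(preset,
    smoke = list(det = 64L, n_angles = 45L, steps_tai = 4L,
                 steps_sand = 6L, n_ref = 3L, photons = 1e4, voxel_um = 1.1,
                 n_slices = 3L),
    benchmark = list(det = 128L, n_angles = 181L, steps_tai = 16L,
                     steps_sand = 20L, n_ref = 5L, photons = 1e4,
                     voxel_um = 1.1, n_slices = 3L),
    paper_scale = list(det = c(2151L, 5120L), n_angles = 3001L,
                       steps_tai = 16L, steps_sand = 20L, n_ref = 70L,
                       photons = 5e4, voxel_um = 1.28, n_slices = 5L)
  )
  det_shape <- if (length(dims$det) == 1) c(dims$det, dims$det) else dims$det
  cfg <- c(base, list(
    detector = detector_model(pixel_um = 1.28, shape_px = det_shape,
                              psf_fwhm_px = 1.67,
                              photons_per_px = dims$photons, dark_level = 10),
    phantom_shape = c(det_shape[1], det_shape[2], det_shape[2]),
    voxel_um = 1.28,  # phantom voxels sampled on the detector grid
    n_angles = dims$n_angles, steps_tai = dims$steps_tai,
    steps_sand = dims$steps_sand, n_ref = dims$n_ref,
    n_slices = dims$n_slices
  ))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML file of overrides on top of a preset. Recognised top-level
#' keys: `preset`, `seed`, `energy_keV`, `n_angles`, `steps_tai`,
#' `steps_sand`, `n_ref`, `photons_per_px`, `detector_px`, `border_px`,
#' `noise`, `drift_px`, `ring` (list with `low_cut`, `high_cut`, `order`),
#' `match` (list with `window_half_px`, `search_radius_px`, `subpixel`,
#' `estimate_darkfield`). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a [preset_config()]-style `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("preset", "seed", "energy_keV", "n_angles", "steps_tai",
             "steps_sand", "n_ref", "photons_per_px", "detector_px",
             "border_px", "noise", "drift_px", "ring", "match")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- preset_config(y$preset %||% "smoke", seed = y$seed %||% 1)
  if (!is.null(y$energy_keV)) cfg$beam <- beam_config(y$energy_keV)
  for (k in c("n_angles", "steps_tai", "steps_sand", "n_ref", "border_px"))
    if (!is.null(y[[k]])) cfg[[k]] <- as.integer(y[[k]])
  if (!is.null(y$noise)) cfg$noise <- isTRUE(y$noise)
  if (!is.null(y$drift_px)) cfg$drift_px <- as.numeric(y$drift_px)
  if (!is.null(y$detector_px) || !is.null(y$photons_per_px)) {
    shp <- if (!is.null(y$detector_px)) rep(as.integer(y$detector_px),
                                            length.out = 2)
           else cfg$detector$shape_px
    cfg$detector <- detector_model(
      pixel_um = cfg$detector$pixel_um, shape_px = shp,
      psf_fwhm_px = cfg$detector$psf_fwhm_px,
      photons_per_px = y$photons_per_px %||% cfg$detector$photons_per_px,
      dark_level = cfg$detector$dark_level)
    cfg$phantom_shape <- c(shp[1], shp[2], shp[2])
  }
  if (!is.null(y$ring)) cfg$ring <- utils::modifyList(cfg$ring, y$ring)
  if (!is.null(y$match))
    cfg$match <- do.call(match_config, utils::modifyList(
      list(window_half_px = cfg$match$window_half_px,
           search_radius_px = cfg$match$search_radius_px,
           subpixel = cfg$match$subpixel,
           estimate_darkfield = cfg$match$estimate_darkfield), y$match))
  cfg
}

# find an all-`label` square ROI of the given size in a label slice,
# preferring positions near `prefer` (row, col); deterministic
find_homogeneous_roi <- function(label_slice, label, size, prefer = NULL,
                                 role = "background", stride = 2) {
  nr <- nrow(label_slice); nc <- ncol(label_slice)
  ok_r <- seq(1, nr - size + 1, by = stride)
  ok_c <- seq(1, nc - size + 1, by = stride)
  is_lab <- label_slice == label
  cs <- matrix(0, nr + 1, nc + 1)
  cs[-1, -1] <- t(apply(apply(is_lab, 2, cumsum), 1, cumsum))
  best <- NULL; best_d <- Inf
  prefer <- prefer %||% c(nr / 2, nc / 2)
  for (r in ok_r) for (c_ in ok_c) {
    s <- cs[r + size, c_ + size] - cs[r, c_ + size] - cs[r + size, c_] +
      cs[r, c_]
    if (s == size * size) {
      d <- (r + size / 2 - prefer[1])^2 + (c_ + size / 2 - prefer[2])^2
      if (d < best_d) { best_d <- d; best <- c(r, c_) }
    }
  }
  if (is.null(best)) return(NULL)
  roi_spec(best, c(size, size), role)
}

# preprocessing shared by both MBI arms: dark subtraction, beam-profile
# normalisation, bad-pixel repair
.condition_frame <- function(raw, dark_mean, profile, badpixel_sigma = 6) {
  img <- (raw - dark_mean) / profile
  replace_bad_pixels(img, badpixel_sigma)
}

# run one MBI arm (streaming over angles); returns recon slices + metrics
# ingredients
run_mbi_arm <- function(cfg, phantom, screen, stepping, arm_seed,
                        slices = NULL, progress = FALSE) {
  det <- cfg$detector; beam <- cfg$beam; geo <- cfg$geometry_mbi
  shp <- det$shape_px
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(arm_seed)
  offs <- stepping$offsets_px
  n_step <- nrow(offs)
  angles <- seq(0, 180, length.out = cfg$n_angles + 1)[seq_len(cfg$n_angles)]
  slices <- slices %||%
    (round(shp[1] / 2) + seq_len(cfg$n_slices) - (cfg$n_slices + 1) %/% 2)

  # screen fields at the sample plane, one per step
  fields <- lapply(seq_len(n_step), function(s)
    fresnel_propagate(screen_field(screen, shp, offs[s, ], beam),
                      geo$z0_m, beam, det$pixel_um))

  dark_mean <- matrix(det$dark_level, shp[1], shp[2])
  refs_raw <- lapply(seq_len(n_step), function(s) {
    acc <- 0
    for (r in seq_len(cfg$n_ref))
      acc <- acc + simulate_frame(geo, beam, det, screen = screen,
                                  noise = cfg$noise,
                                  sample_plane_field = fields[[s]])
    acc / cfg$n_ref
  })
  profile <- estimate_beam_profile(
    lapply(refs_raw, function(m) m - dark_mean), kernel_px = 51)
  refs <- lapply(refs_raw, .condition_frame, dark_mean = dark_mean,
                 profile = profile)

  # pattern characterisation on the first conditioned reference
  vis <- visibility_map(refs[[1]], window_px = 15)
  fwhm <- autocorr_fwhm(refs[[1]])

  # the phantom column crosses the full frame height, so only the left/right
  # margins are sample-free
  mask <- border_mask(shp, cfg$border_px, sides = "cols")
  n_det <- shp[2]
  phi_sino <- array(0, c(cfg$n_angles, n_det, length(slices)))
  T_sino <- array(0, c(cfg$n_angles, n_det, length(slices)))
  alpha_first <- NULL
  for (j in seq_len(cfg$n_angles)) {
    pr <- project_phantom(phantom, angles[j])
    sam <- lapply(seq_len(n_step), function(s)
      .condition_frame(
        simulate_frame(geo, beam, det, screen = screen, phantom = phantom,
                       angle_deg = angles[j], noise = cfg$noise,
                       projection = pr, sample_plane_field = fields[[s]]),
        dark_mean, profile))
    mm <- umpa_match(sam, refs, cfg$match)
    al <- displacements_to_angles(mm, det, geo)
    if (j == 1) alpha_first <- al
    gf <- angles_to_dpc(al, beam, det$pixel_um)
    gf <- detrend_dpc(gf, mask)
    pp <- fourier_integrate(gf)
    pp <- detrend_phase(pp, mask)
    phi_sino[j, , ] <- t(pp$phi[slices, , drop = FALSE])
    T_sino[j, , ] <- t(mm$T[slices, , drop = FALSE])
    if (progress && j %% 50 == 0) message("  angle ", j, "/", cfg$n_angles)
  }

  k <- beam$wavenumber
  delta_sino <- -phi_sino / k
  beta_sino <- -log(pmax(T_sino, 1e-6)) / (2 * k)
  for (sl in seq_along(slices)) {
    delta_sino[, , sl] <- ring_filter(delta_sino[, , sl], cfg$ring$low_cut,
                                      cfg$ring$high_cut, cfg$ring$order)
    beta_sino[, , sl] <- ring_filter(beta_sino[, , sl], cfg$ring$low_cut,
                                     cfg$ring$high_cut, cfg$ring$order)
  }
  recon_d <- fbp_reconstruct(delta_sino, angles, det$pixel_um, "delta")
  recon_b <- fbp_reconstruct(beta_sino, angles, det$pixel_um, "beta")
  list(delta = recon_d, beta = recon_b, alpha_first = alpha_first,
       visibility = vis, fwhm_px = fwhm, slices = slices, angles = angles)
}

# run the PBI arm
run_pbi_arm <- function(cfg, phantom, gamma, arm_seed, slices = NULL,
                        progress = FALSE) {
  det <- cfg$detector; beam <- cfg$beam; geo <- cfg$geometry_pbi
  shp <- det$shape_px
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(arm_seed)
  angles <- seq(0, 180, length.out = cfg$n_angles + 1)[seq_len(cfg$n_angles)]
  slices <- slices %||%
    (round(shp[1] / 2) + seq_len(cfg$n_slices) - (cfg$n_slices + 1) %/% 2)
  dark_mean <- matrix(det$dark_level, shp[1], shp[2])
  flat <- 0
  for (r in seq_len(max(cfg$n_ref, 3)))
    flat <- flat + simulate_frame(geo, beam, det, noise = cfg$noise)
  flat <- flat / max(cfg$n_ref, 3)
  pag <- paganin_config(gamma = gamma, z_m = geo$z_prop_m,
                        energy_keV = beam$energy_keV,
                        pixel_um = det$pixel_um)
  phi_sino <- array(0, c(cfg$n_angles, shp[2], length(slices)))
  for (j in seq_len(cfg$n_angles)) {
    raw <- simulate_frame(geo, beam, det, phantom = phantom,
                          angle_deg = angles[j], noise = cfg$noise)
    ratio <- correct_dark_flat(raw, dark_mean, flat)
    ratio <- replace_bad_pixels(ratio)
    ratio[ratio <= 0] <- 1e-6
    pp <- paganin_filter(ratio, pag)
    phi_sino[j, , ] <- t(pp$phi[slices, , drop = FALSE])
    if (progress && j %% 50 == 0) message("  angle ", j, "/", cfg$n_angles)
  }
  k <- beam$wavenumber
  delta_sino <- -phi_sino / k
  for (sl in seq_along(slices))
    delta_sino[, , sl] <- ring_filter(delta_sino[, , sl], cfg$ring$low_cut,
                                      cfg$ring$high_cut, cfg$ring$order)
  recon_d <- fbp_reconstruct(delta_sino, angles, det$pixel_um, "delta")
  list(delta = recon_d, slices = slices, angles = angles)
}

#' Run the three-arm phase-contrast comparison experiment
#'
#' Simulates MBI-with-TAI, MBI-with-sandpaper and PBI scans of the same
#' phantom with the same seed, reconstructs aligned slices, and assembles a
#' per-arm image-quality report (visibility, speckle FWHM, resolution,
#' angular sensitivity, phase sensitivity, CNR).
#'
#' @param config a [preset_config()].
#' @param out_dir optional directory; when given, the report CSV and a
#'   side-by-side slice gallery PNG are written there.
#' @param arms subset of `c("mbi_tai", "mbi_sandpaper", "pbi")` to run.
#' @param progress print per-stage progress messages.
#' @return list with `report` (data frame, one row per arm), `volumes`
#'   (named list of delta [fbp_reconstruct()] results), `rois`, `phantom`,
#'   `config`.
#' @export
run_experiment <- function(config = preset_config("smoke"), out_dir = NULL,
                           arms = c("mbi_tai", "mbi_sandpaper", "pbi"),
                           progress = FALSE) {
  cfg <- config
  det <- cfg$detector; shp <- det$shape_px
  phan <- make_placenta_phantom(cfg$phantom_shape, cfg$voxel_um,
                                seed = cfg$seed,
                                energy_keV = cfg$beam$energy_keV)
  slices <- round(shp[1] / 2) +
    seq_len(cfg$n_slices) - (cfg$n_slices + 1) %/% 2

  # ROIs from the ground-truth labels of the central slice (shared by arms)
  lab_mid <- phan$label_volume[slices[(length(slices) + 1) %/% 2], , ]
  lab_all <- phan$label_volume[slices, , , drop = FALSE]
  roi_size <- max(8L, min(40L, floor(min(shp) / 5)))
  stem <- c((dim(lab_mid)[1] + 1) / 2 + 0.16 * dim(lab_mid)[1],
            (dim(lab_mid)[2] + 1) / 2)
  lab_common <- apply(lab_all, c(2, 3), function(v)
    if (all(v == v[1])) v[1] else -1L)
  sig_roi <- find_homogeneous_roi(lab_common, 2L, max(6L, roi_size %/% 3),
                                  prefer = stem, role = "signal")
  bg_roi <- find_homogeneous_roi(lab_common, 1L, roi_size, role = "background")
  check_that(!is.null(sig_roi) && !is.null(bg_roi),
             "phantom has no homogeneous tissue/paraffin ROI at this scale")
  # corner ROI fully in air: the paraffin cylinder (radius 0.42 * width)
  # leaves the frame corners free up to ~0.2 * width from the edge
  margin <- 2L
  air_size <- max(6L, min(16L, floor(0.2 * min(shp)) - margin - 1L))
  air_roi <- roi_spec(c(margin + 1L, margin + 1L), c(air_size, air_size),
                      "background")

  screens_shape <- shp + 32L  # margin for stepping offsets
  gamma_pair <- tune_gamma("soft_tissue", "paraffin", cfg$beam$energy_keV)

  results <- list(); report <- NULL
  for (arm in arms) {
    if (progress) message("arm: ", arm)
    if (arm == "mbi_tai") {
      screen <- make_tai_screen(cfg$tai$period_um, cfg$tai$duty_cycle,
                                cfg$tai$etch_depth_um, cfg$tai$material,
                                det$pixel_um, screens_shape)
      stepping <- stepping_pattern("tilted_grid", cfg$steps_tai,
                                   cfg$tai$period_um, det$pixel_um)
      res <- run_mbi_arm(cfg, phan, screen, stepping, cfg$seed + 101,
                         slices, progress)
    } else if (arm == "mbi_sandpaper") {
      screen <- make_sandpaper_screen(cfg$sandpaper$grain_mean_um,
                                      cfg$sandpaper$n_layers,
                                      cfg$sandpaper$material, det$pixel_um,
                                      screens_shape, seed = cfg$seed + 7)
      stepping <- stepping_pattern("spiral", cfg$steps_sand,
                                   pixel_um = det$pixel_um)
      res <- run_mbi_arm(cfg, phan, screen, stepping, cfg$seed + 202,
                         slices, progress)
    } else {
      res <- run_pbi_arm(cfg, phan, gamma_pair, cfg$seed + 303, slices,
                         progress)
    }
    results[[arm]] <- res

    mid <- (length(res$slices) + 1) %/% 2
    dslice <- res$delta$values[mid, , ]
    rho <- delta_to_electron_density(res$delta, cfg$beam)
    row <- metrics_report(
      method = arm,
      mean_visibility = if (!is.null(res$visibility))
        res$visibility$mean_visibility else NA,
      autocorr_fwhm_px = res$fwhm_px %||% NA,
      resolution_um = tryCatch(
        as.numeric(fourier_resolution(dslice, bg_roi, det$pixel_um)),
        error = function(e) NA),
      sigma_alpha_x_nrad = if (!is.null(res$alpha_first))
        angular_sensitivity(res$alpha_first, air_roi)[["sigma_x_nrad"]] else NA,
      sigma_alpha_y_nrad = if (!is.null(res$alpha_first))
        angular_sensitivity(res$alpha_first, air_roi)[["sigma_y_nrad"]] else NA,
      sigma_rho_e = suppressWarnings(phase_sensitivity(rho, bg_roi)),
      cnr_mean = cnr(dslice, sig_roi, bg_roi),
      cnr_sd = stats::sd(vapply(seq_along(res$slices), function(i)
        cnr(res$delta$values[i, , ], sig_roi, bg_roi), numeric(1))),
      pixel_um = det$pixel_um)
    report <- rbind(report, row)
  }

  out <- list(report = report,
              volumes = lapply(results, `[[`, "delta"),
              results = results,
              rois = list(signal = sig_roi, background = bg_roi,
                          air = air_roi),
              phantom = phan, gamma = gamma_pair, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report, file.path(out_dir, "metrics_report.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "slice_gallery.png"),
                   width = 320 * length(results), height = 360)
    old_par <- graphics::par(mfrow = c(1, length(results)), mar = c(1, 1, 2, 1))
    for (arm in names(results)) {
      mid <- (length(results[[arm]]$slices) + 1) %/% 2
      sl <- results[[arm]]$delta$values[mid, , ]
      graphics::image(sl, col = grDevices::gray.colors(256), axes = FALSE,
                      main = arm, useRaster = TRUE)
    }
    graphics::par(old_par)
    grDevices::dev.off()
  }
  out
}
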