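test_that("flat frame without noise is uniform at photons_per_px", {
  det <- detector_model(shape_px = c(32, 32), photons_per_px = 5e3)
  img <- simulate_frame(scan_geometry(), beam_config(), det, noise = FALSE)
  expect_equal(max(abs(img - 5e3)), 0, tolerance = 1e-6)
})

test_that("absorbing-only phantom at vanishing propagation obeys Beer-Lambert", {
  n <- 32
  lab <- array(0L, c(n, n, n)); lab[8:24, 8:24, 8:24] <- 1L
  # absorbing, non-refracting custom material
  mat <- list(`0` = list(material_name = "vac", delta = 0, beta = 0),
              `1` = list(material_name = "abs", delta = 0, beta = 5e-9))
  ph <- phantom(lab, mat, voxel_um = 1.28)
  b <- beam_config(20)
  det <- detector_model(shape_px = c(n, n), psf_fwhm_px = 0,
                        photons_per_px = 1)
  geo <- scan_geometry(z_prop_m = 1e-9)
  img <- simulate_frame(geo, b, det, phantom = ph, angle_deg = 0,
                        noise = FALSE)
  pr <- project_phantom(ph, 0)
  expected <- exp(-2 * b$wavenumber * pr$beta_t_map)
  expect_lt(max(abs(img - expected)), 1e-4)
})

test_that("a pure-phase object is invisible without propagation", {
  n <- 32
  lab <- array(0L, c(n, n, n)); lab[8:24, 8:24, 8:24] <- 1L
  mat <- list(`0` = list(material_name = "vac", delta = 0, beta = 0),
              `1` = list(material_name = "ph", delta = 1e-6, beta = 0))
  ph <- phantom(lab, mat, voxel_um = 1.28)
  det <- detector_model(shape_px = c(n, n), psf_fwhm_px = 0,
                        photons_per_px = 1)
  img <- simulate_frame(scan_geometry(z_prop_m = 1e-12), beam_config(),
                        det, phantom = ph, noise = FALSE)
  expect_lt(max(img) - min(img), 1e-6)
})

test_that("TAI reference frames show stable visibility across angles", {
  fx <- tai_fixture()
  ph <- make_placenta_phantom(c(64, 64, 64), 1.28, seed = 3)
  v <- vapply(c(0, 60, 120), function(ang)
    visibility_map(simulate_frame(fx$geo, fx$beam, fx$det, screen = fx$screen,
                                  phantom = NULL, angle_deg = ang,
                                  noise = FALSE,
                                  sample_plane_field = fx$fields[[1]]))$mean_visibility,
    numeric(1))
  expect_true(all(v > 0.05))
  expect_lt(diff(range(v)) / mean(v), 0.01)  # reference has no angle dependence
})

test_that("simulate_scan is deterministic and reduces to simulate_frame", {
  ph <- make_placenta_phantom(c(24, 24, 24), 1.28, seed = 1)
  det <- detector_model(shape_px = c(24, 24), photons_per_px = 1e3,
                        n_dark = 2, dark_level = 5)
  cfg <- scan_config(detector = det, phantom = ph, n_angles = 2, n_ref = 2,
                     seed = 42)
  s1 <- simulate_scan(cfg)
  s2 <- simulate_scan(cfg)
  expect_identical(s1$sample, s2$sample)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$dark, s2$dark)
  # single step/angle, no noise: the sample plane equals one simulate_frame
  cfg1 <- scan_config(detector = det, phantom = ph, n_angles = 1, n_ref = 1,
                      noise = FALSE, seed = 1)
  s <- simulate_scan(cfg1)
  direct <- simulate_frame(cfg1$geometry, cfg1$beam, det, phantom = ph,
                           angle_deg = 0, noise = FALSE)
  expect_equal(s$sample[1, 1, , ], direct, tolerance = 1e-12)
  # ground truth phase present
  expect_equal(length(s$ground_truth$phi), 1)
  expect_true(all(is.finite(s$ground_truth$phi[[1]])))
})

test_that("averaging stepped references removes the modulation", {
  fx <- tai_fixture()
  stack_mean <- Reduce(`+`, fx$refs) / length(fx$refs)
  v_single <- visibility_map(fx$refs[[1]])$mean_visibility
  v_mean <- visibility_map(stack_mean)$mean_visibility
  expect_lt(v_mean, 0.5 * v_single)
})

test_that("zero drift gives reference frames identical up to noise", {
  det <- detector_model(shape_px = c(32, 32), photons_per_px = 1e3)
  scr <- make_tai_screen(shape_px = c(48, 48))
  cfg <- scan_config(detector = det, screen = scr, n_angles = 3, n_ref = 2,
                     noise = FALSE, drift_px = c(0, 0), seed = 9)
  s <- simulate_scan(cfg)
  expect_equal(s$reference[1, 1, , ], s$reference[1, 2, , ],
               tolerance = 1e-12)
})
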