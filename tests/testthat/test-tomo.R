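make_disk_sino <- function(n_ang, n_det, r, value, centre_off = 0,
                           pixel_um = 1.28, blur = 0) {
  angles <- seq(0, 180, length.out = n_ang + 1)[seq_len(n_ang)]
  cx <- (n_det + 1) / 2
  u <- seq_len(n_det) - cx
  th <- angles * pi / 180
  sino <- matrix(0, n_ang, n_det)
  for (a in seq_len(n_ang)) {
    up <- u + centre_off * sin(th[a])
    prof <- 2 * sqrt(pmax(r^2 - up^2, 0)) * pixel_um * 1e-6 * value
    if (blur > 0) prof <- xpci:::gauss_blur(matrix(prof, 1), blur)[1, ]
    sino[a, ] <- prof
  }
  list(sino = sino, angles = angles)
}

test_that("ring filter passes stripe-free sinograms through unchanged", {
  # the filter subtracts the band-passed angle-mean; data without an
  # angle-stationary component pass through exactly
  n_ang <- 180; n <- 128
  a_idx <- seq_len(n_ang)
  u <- seq_len(n) - (n + 1) / 2
  # zero angle-mean by construction (full cosine periods over the scan)
  sino <- outer(cos(2 * pi * a_idx / n_ang), exp(-u^2 / (2 * 20^2)))
  out <- ring_filter(sino)
  expect_lt(max(abs(out - sino)) / max(abs(sino)), 1e-12)
  # a smooth, slowly rotating envelope is perturbed by well under the
  # Butterworth leakage bound of its angle-mean
  th <- seq(0, 180, length.out = 182)[1:181] * pi / 180
  sino2 <- t(vapply(th, function(a) exp(-(u + 15 * sin(a))^2 / (2 * 40^2)),
                    numeric(n)))
  out2 <- ring_filter(sino2)
  expect_lt(sqrt(mean((out2 - sino2)^2)) / sqrt(mean(sino2^2)), 0.10)
  # zero sinogram stays zero
  expect_equal(max(abs(ring_filter(matrix(0, 50, 64)))), 0)
})

test_that("a perfect ring (constant column offset) is suppressed >= 10x", {
  sino <- matrix(0, 181, 128)
  sino[, 60] <- 1
  out <- ring_filter(sino)
  expect_gte(1 / max(abs(colMeans(out))), 10)
  expect_error(ring_filter(sino, low_cut = 0.3, high_cut = 0.2), "low_cut")
})

test_that("FBP recovers a uniform disk within 2% and a clean exterior", {
  d <- make_disk_sino(181, 128, 40, 1e-6)
  rec <- fbp_reconstruct(d$sino, d$angles, 1.28)
  u <- seq_len(128) - 64.5
  rr <- sqrt(outer(u^2, u^2, `+`))
  interior <- mean(rec$values[1, , ][rr < 37])
  exterior <- mean(rec$values[1, , ][rr > 45])
  expect_lt(abs(interior / 1e-6 - 1), 0.02)
  expect_lt(abs(exterior), 5e-8)
  expect_equal(rec$channel, "delta")
  # zero sinogram reconstructs to zero
  z <- fbp_reconstruct(matrix(0, 181, 64),
                       seq(0, 180, length.out = 182)[1:181], 1.28)
  expect_equal(max(abs(z$values)), 0)
  expect_warning(fbp_reconstruct(matrix(1, 5, 32), seq(0, 144, by = 36), 1.28),
                 "angles")
})

test_that("two-disk phantom contrast is preserved through FBP", {
  big <- make_disk_sino(181, 128, 40, 1e-6)
  small <- make_disk_sino(181, 128, 18, 5e-7)
  rec <- fbp_reconstruct(big$sino + small$sino, big$angles, 1.28)
  u <- seq_len(128) - 64.5
  rr <- sqrt(outer(u^2, u^2, `+`))
  inner <- mean(rec$values[1, , ][rr < 15])       # 1.5e-6 expected
  annulus <- mean(rec$values[1, , ][rr > 22 & rr < 37])  # 1e-6 expected
  expect_lt(abs(inner / annulus - 1.5) / 1.5, 0.02)
})

test_that("electron-density conversion implements the closed-form map", {
  b <- beam_config(20)
  # delta = 5.76e-7 at 20 keV -> ~0.334 electrons/A^3
  rho <- delta_to_electron_density(array(5.76e-7, c(1, 2, 2)), b)
  expect_equal(rho$rho_e[1, 1, 1], 0.334, tolerance = 2e-3)
  expect_equal(delta_to_electron_density(array(0, c(1, 1, 1)), b)$rho_e[1, 1, 1], 0)
  # exact linearity
  r1 <- delta_to_electron_density(array(1e-7, c(1, 1, 1)), b)$rho_e
  r2 <- delta_to_electron_density(array(2e-7, c(1, 1, 1)), b)$rho_e
  expect_equal(r2, 2 * r1)
  # channel guard
  vol <- fbp_reconstruct(matrix(0, 20, 16), seq(0, 171, by = 9), 1.28, "beta")
  expect_error(delta_to_electron_density(vol, b), "delta")
})

test_that("attenuation conversion mu = 2 k beta and its scalings", {
  b <- beam_config(20)
  mu <- beta_to_mu(array(1e-9, c(1, 1, 1)), b)
  expect_equal(mu$mu[1, 1, 1], 2 * (2 * pi / 6.199e-11) * 1e-9,
               tolerance = 1e-4)
  expect_equal(mu$mu[1, 1, 1], 202.7, tolerance = 1e-3)
  expect_equal(beta_to_mu(array(0, c(1, 1, 1)), b)$mu[1, 1, 1], 0)
  # halving lambda (doubling energy) doubles mu at fixed beta
  mu2 <- beta_to_mu(array(1e-9, c(1, 1, 1)), beam_config(40))
  expect_equal(mu2$mu[1, 1, 1], 2 * mu$mu[1, 1, 1])
  vol <- fbp_reconstruct(matrix(0, 20, 16), seq(0, 171, by = 9), 1.28, "delta")
  expect_error(beta_to_mu(vol, b), "beta")
})

test_that("projection then FBP round-trips the phantom's delta", {
  ph <- make_placenta_phantom(c(32, 128, 128), 1.28, seed = 4)
  angles <- seq(0, 180, length.out = 182)[1:181]
  z_mid <- 16
  sino <- t(vapply(angles, function(a)
    project_phantom(ph, a)$delta_t_map[z_mid, ], numeric(128)))
  rec <- fbp_reconstruct(sino, angles, 1.28)
  truth <- ph$ground_truth_delta[z_mid, , ]
  inside_paraffin <- truth == optical_constants("paraffin", 20)$delta
  # erode the mask so only interior paraffin voxels are compared
  er <- inside_paraffin &
    rbind(inside_paraffin[-1, ], FALSE) & rbind(FALSE, inside_paraffin[-128, ]) &
    cbind(inside_paraffin[, -1], FALSE) & cbind(FALSE, inside_paraffin[, -128])
  got <- mean(rec$values[1, , ][er])
  expect_lt(abs(got / optical_constants("paraffin", 20)$delta - 1), 0.02)
})
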