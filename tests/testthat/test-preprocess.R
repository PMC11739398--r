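test_that("dark/flat correction inverts the detector model algebraically", {
  set.seed(1)
  n <- 48
  dark <- matrix(100 + rnorm(n^2), n)
  flat <- matrix(5000 * (1 + 0.2 * outer(sin(1:n / 9), cos(1:n / 7))), n)
  t_map <- matrix(runif(n^2, 0.4, 1), n)
  raw <- (flat - dark) * t_map + dark
  out <- correct_dark_flat(raw, dark, flat)
  expect_equal(out, t_map, tolerance = 1e-12)
  expect_equal(correct_dark_flat(flat, dark, flat),
               matrix(1, n, n), tolerance = 1e-12)
  expect_equal(correct_dark_flat(dark, dark, flat),
               matrix(0, n, n), tolerance = 1e-12)
  # a large non-positive denominator region is an error
  bad_flat <- flat; bad_flat[, 1:10] <- 0
  expect_error(correct_dark_flat(raw, dark, bad_flat), "denominator")
})

test_that("bad-pixel repair fixes outliers, is idempotent, leaves clean pixels", {
  ramp <- outer(1:80, 1:80, function(i, j) 0.5 * i + 0.2 * j)
  out0 <- replace_bad_pixels(ramp, 6)
  expect_equal(as.vector(out0), as.vector(ramp))  # clean image unchanged
  img <- ramp
  img[40, 40] <- 1e4                              # single hot pixel
  out1 <- replace_bad_pixels(img, 6)
  expect_lt(abs(out1[40, 40] - ramp[40, 40]), 0.8)
  set.seed(3)
  idx <- sample(6400, 100)
  img2 <- ramp
  img2[idx] <- img2[idx] + sample(c(-60, 60, 120), 100, replace = TRUE)
  rep1 <- replace_bad_pixels(img2, 6)
  expect_lt(max(abs(rep1 - ramp)), 1)             # below the ramp local step
  rep2 <- replace_bad_pixels(rep1, 6)
  expect_equal(as.vector(rep2), as.vector(rep1))  # idempotent
  # NA pixels are treated as bad and repaired
  img3 <- ramp; img3[10, 10] <- NA
  expect_true(is.finite(replace_bad_pixels(img3, 6)[10, 10]))
  # overwhelming corruption is rejected
  img4 <- ramp; img4[sample(6400, 1000)] <- 1e5
  expect_error(replace_bad_pixels(img4, 6), "flagged")
})

test_that("beam profile estimation recovers the smooth illumination", {
  n <- 96
  smooth <- 1000 * (1 + 0.3 * outer(exp(-((1:n) - 48)^2 / 12000),
                                    exp(-((1:n) - 48)^2 / 15000)))
  set.seed(4)
  speckle <- matrix(runif(n^2, 0.6, 1.4), n)
  frames <- lapply(1:4, function(i) smooth * speckle)
  prof <- estimate_beam_profile(frames, 51)
  i <- 26:70
  expect_lt(max(abs(prof[i, i] - smooth[i, i]) / smooth[i, i]), 0.02)
  # constant frames give a constant profile
  const <- estimate_beam_profile(matrix(7, 20, 20), 15)
  expect_equal(const, matrix(7, 20, 20), tolerance = 1e-12)
  # kernel at least as large as the image gives the global mean
  big <- estimate_beam_profile(smooth, 301)
  expect_equal(big, matrix(mean(smooth), n, n), tolerance = 1e-12)
  expect_error(estimate_beam_profile(matrix(-1, 8, 8), 5), "non-positive")
})

# drift registration is exercised on the aperiodic diffuser pattern; a
# periodic TAI pattern makes the correlation peak ambiguous beyond half a
# lattice period, which is why diffusers are the standard drift reference
sandpaper_ref <- function() {
  if (!is.null(.fixtures$sand_ref)) return(.fixtures$sand_ref)
  b <- beam_config(20)
  det <- detector_model(shape_px = c(96, 96), photons_per_px = 1e4)
  sp <- make_sandpaper_screen(shape_px = c(128, 128), seed = 5)
  .fixtures$sand_ref <- simulate_frame(scan_geometry(), b, det, screen = sp,
                                       noise = FALSE)
  .fixtures$sand_ref
}

test_that("drift correction recovers injected rigid shifts to 0.05 px", {
  ref <- sandpaper_ref()
  errs <- c()
  for (dy in c(-3, -1.3, 0, 2.7)) for (dx in c(-2.1, 0, 1.9)) {
    sam <- xpci:::fourier_shift(ref, dy, dx)
    cd <- correct_drift(sam, ref, upsample = 40)
    errs <- c(errs, cd$shift_px - c(dy, dx))
  }
  expect_lt(sqrt(mean(errs^2)), 0.05)
  # matched reference aligns with the drifted pattern
  sam <- xpci:::fourier_shift(ref, 1.3, -0.6)
  cd <- correct_drift(sam, ref, upsample = 40)
  expect_lt(mean((cd$matched_reference - sam)^2) / stats::var(as.vector(sam)),
            1e-3)
})

test_that("drift recovery is robust to photon noise at 1e4 photons", {
  ref <- sandpaper_ref()
  set.seed(8)
  sam <- matrix(stats::rpois(length(ref),
                             pmax(xpci:::fourier_shift(ref, 1.0, -2.0), 0)),
                nrow(ref))
  refn <- matrix(stats::rpois(length(ref), ref), nrow(ref))
  cd <- correct_drift(sam, refn, upsample = 40)
  expect_lt(max(abs(cd$shift_px - c(1, -2))), 0.1)
})

test_that("a patternless frame triggers the weak-correlation warning", {
  flat <- matrix(1000, 48, 48)
  set.seed(5)
  noisy <- matrix(rnorm(48^2, 1000, 1), 48)
  expect_warning(cd <- correct_drift(noisy, flat, upsample = 10), "weak")
  expect_equal(cd$shift_px, c(0, 0))
})

test_that("flat-correcting flats then estimating the profile gives ones", {
  set.seed(11)
  dark <- matrix(10, 48, 48)
  flat_mean <- matrix(2000 * (1 + 0.1 * outer(sin((1:48) / 30),
                                              cos((1:48) / 25))), 48)
  flats <- lapply(1:6, function(i)
    matrix(stats::rpois(48^2, flat_mean - 10) + 10, 48))
  corr <- lapply(flats, correct_dark_flat, dark_mean = dark,
                 flat_mean = flat_mean)
  prof <- estimate_beam_profile(corr, 25)
  expect_lt(max(abs(prof - 1)), 0.01)   # ones within noise
})
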