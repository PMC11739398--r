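test_that("matching a stack against itself returns the identity signal", {
  fx <- tai_fixture()
  mm <- umpa_match(fx$refs, fx$refs)
  expect_equal(max(abs(c(mm$u_x, mm$u_y))), 0)
  expect_lt(max(abs(mm$T - 1)), 1e-3)
  expect_lt(max(abs(mm$D - 1)), 1e-3)
  expect_lt(max(mm$residual) / mean(fx$refs[[1]])^2, 1e-6)
})

test_that("an attenuated, integer-shifted copy is recovered exactly", {
  fx <- tai_fixture()
  sam <- lapply(fx$refs, function(r) 0.8 * xpci:::shift_int(r, 0, 2))
  mm <- umpa_match(sam, fx$refs)
  i <- 8:56
  expect_lt(max(abs(mm$T[i, i] - 0.8)), 1e-3)
  expect_lt(max(abs(mm$u_x[i, i] - 2)), 0.05)
  expect_lt(max(abs(mm$u_y[i, i])), 0.05)
  expect_lt(max(abs(mm$D[i, i] - 1)), 0.01)
})

test_that("pattern blur maps to a dark-field signal near the modulation loss", {
  fx <- tai_fixture()
  sam <- lapply(fx$refs, xpci:::gauss_blur, sigma = 1.0)
  # modulation loss factor measured directly on the stacks
  rbar <- Reduce(`+`, fx$refs) / 16
  sbar <- Reduce(`+`, sam) / 16
  mod_r <- sqrt(mean(Reduce(`+`, lapply(fx$refs, function(m) (m - rbar)^2)) / 16))
  mod_s <- sqrt(mean(Reduce(`+`, lapply(sam, function(m) (m - sbar)^2)) / 16))
  f <- mod_s / mod_r
  mm <- umpa_match(sam, fx$refs)
  i <- 8:56
  expect_lt(abs(mean(mm$D[i, i]) - f), 0.05)
  expect_lt(abs(mean(mm$u_x[i, i])), 0.05)
})

test_that("discrete minimiser equals per-pixel brute force on small stacks", {
  # independent oracle: direct per-pixel loops over candidates and window
  fx <- tai_fixture()
  n <- 32; M <- 4
  refs <- lapply(fx$refs[1:M], function(r) r[1:n, 1:n])
  sam <- lapply(refs, function(r) 0.9 * xpci:::shift_int(r, 1, -1))
  h <- 1L; sr <- 2L
  cfg <- match_config(h, sr, subpixel = "refine_off")
  mm <- umpa_match(sam, refs, cfg)

  rbar <- Reduce(`+`, refs) / M
  # independent per-pixel evaluation of the windowed least-squares cost
  brute_best2 <- function(py, px) {
    best <- c(NA, NA); bc <- Inf
    for (dx in -sr:sr) for (dy in -sr:sr) {
      s1 <- s2 <- s3 <- s4 <- s5 <- 0
      for (wy in -h:h) for (wx in -h:h) {
        y <- py + wy; x <- px + wx
        if (y < 1 || y > n || x < 1 || x > n) next
        ys <- ((y - 1 - dy) %% n) + 1; xs <- ((x - 1 - dx) %% n) + 1
        a <- rbar[ys, xs]
        for (m in 1:M) {
          rm <- refs[[m]][ys, xs]; sm <- sam[[m]][y, x]
          s1 <- s1 + sm^2; s3 <- s3 + a * sm
          s4 <- s4 + (rm - a)^2; s5 <- s5 + (rm - a) * sm
          s2 <- s2 + a^2
        }
      }
      cost <- s1 - (if (s2 > 0) s3^2 / s2 else 0) -
        (if (s4 > .Machine$double.eps) s5^2 / s4 else 0)
      if (cost < bc) { bc <- cost; best <- c(dy, dx) }
    }
    best
  }
  set.seed(10)
  pts <- cbind(sample(5:(n - 4), 40, replace = TRUE),
               sample(5:(n - 4), 40, replace = TRUE))
  for (k in seq_len(nrow(pts))) {
    bb <- brute_best2(pts[k, 1], pts[k, 2])
    expect_equal(unname(mm$u_y[pts[k, 1], pts[k, 2]]), bb[1])
    expect_equal(unname(mm$u_x[pts[k, 1], pts[k, 2]]), bb[2])
  }
})

test_that("more modulator steps do not degrade displacement recovery", {
  fx <- tai_fixture()
  shift_err <- function(n_steps) {
    refs <- fx$refs[seq_len(n_steps)]
    sam <- lapply(refs, function(r) xpci:::fourier_shift(r, 0.4, -0.7))
    mm <- umpa_match(sam, refs, match_config(1, 2))
    i <- 8:56
    sqrt(mean((mm$u_x[i, i] + 0.7)^2 + (mm$u_y[i, i] - 0.4)^2))
  }
  expect_lte(shift_err(16), shift_err(4) + 0.01)
})

test_that("displacement-to-angle and angle-to-DPC conversions are exact", {
  det <- detector_model(pixel_um = 1.28)
  geo <- scan_geometry(z_prop_m = 0.175)
  u <- list(u_x = matrix(1, 2, 2), u_y = matrix(0, 2, 2))
  al <- displacements_to_angles(u, det, geo)
  expect_equal(al$alpha_x[1, 1], 1.28e-6 / 0.175)       # 7.314 urad
  expect_equal(al$alpha_x[1, 1] * 1e6, 7.314, tolerance = 1e-3)
  expect_equal(al$alpha_y[1, 1], 0)
  # doubling z_eff halves the angle exactly
  al2 <- displacements_to_angles(u, det, geo, z_eff_m = 0.35)
  expect_equal(al2$alpha_x, al$alpha_x / 2)
  expect_error(displacements_to_angles(u, det, geo, z_eff_m = -1), "z_eff")
  b <- beam_config(20)
  gf <- angles_to_dpc(al, b, det$pixel_um)
  expect_equal(gf$gx, b$wavenumber * al$alpha_x)
  # linearity
  al3 <- list(alpha_x = 2 * al$alpha_x, alpha_y = 2 * al$alpha_y)
  gf3 <- angles_to_dpc(al3, b, det$pixel_um)
  expect_equal(gf3$gx, 2 * gf$gx)
  # zero angles give zero gradients
  expect_equal(max(abs(angles_to_dpc(list(alpha_x = matrix(0, 2, 2),
                                          alpha_y = matrix(0, 2, 2)),
                                     b, 1.28)$gx)), 0)
})

test_that("degenerate windows without reference modulation are flagged", {
  flat_refs <- lapply(1:4, function(i) matrix(1000, 24, 24))
  sam <- lapply(1:4, function(i) matrix(800, 24, 24))
  mm <- umpa_match(sam, flat_refs, match_config(1, 1, "refine_off"))
  expect_gt(mm$n_degenerate, 0)
  expect_true(all(mm$D == 1))
  expect_lt(max(abs(mm$T - 0.8)), 1e-10)
})

test_that("a smoothly varying pure absorber is recovered in T within 0.01", {
  fx <- tai_fixture()
  xx <- matrix(seq_len(64) / 64, 64, 64, byrow = TRUE)
  t_true <- 0.7 + 0.25 * xpci:::gauss_blur(sin(2 * pi * xx) * t(xx), 6)
  sam <- lapply(fx$refs, function(r) t_true * r)
  mm <- umpa_match(sam, fx$refs)
  i <- 8:56
  expect_lt(max(abs(mm$T[i, i] - t_true[i, i])), 0.01)
  expect_lt(max(abs(mm$u_x[i, i])), 0.1)
})
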