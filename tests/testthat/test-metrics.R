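test_that("visibility is zero for constants, scale-invariant, and exact on
           a two-valued pattern", {
  expect_equal(max(visibility_map(matrix(7, 32, 32))$values), 0)
  fx <- tai_fixture()
  v1 <- visibility_map(fx$refs[[1]])
  v2 <- visibility_map(3.7 * fx$refs[[1]])
  expect_equal(v1$values, v2$values, tolerance = 1e-12)
  expect_equal(v1$mean_visibility, mean(v1$values))
  # two-valued pattern: population std over mean evaluated on the window
  # content; with equal fill this reduces to |a - b| / (a + b)
  a <- 2; b <- 6
  chk <- matrix(c(a, b), 10, 12)          # rows alternate a,b,a,b
  vm <- visibility_map(chk, 3)
  w <- chk[4:6, 4:6]
  expect_equal(vm$values[5, 5],
               sqrt(mean((w - mean(w))^2)) / mean(w), tolerance = 1e-12)
  # equal-fill reduction checked directly on one window's values
  w_eq <- c(a, a, b, b)
  expect_equal(sqrt(mean((w_eq - mean(w_eq))^2)) / mean(w_eq),
               abs(a - b) / (a + b))
  expect_error(visibility_map(chk, 2), "window")
})

test_that("autocorrelation FWHM: white-noise limit, Gaussian oracle,
           contrast invariance", {
  set.seed(1)
  wn <- matrix(rnorm(256^2, 100, 5), 256)
  expect_lte(autocorr_fwhm(wn), 2)
  # Gaussian-filtered white noise: autocorrelation is Gaussian with
  # sigma * sqrt(2) -> FWHM = 2.3548 * sigma * sqrt(2)
  for (sig in c(1.5, 2.5)) {
    g <- xpci:::gauss_blur(matrix(rnorm(256^2), 256), sig)
    expect_equal(autocorr_fwhm(g), 2.3548 * sig * sqrt(2), tolerance = 0.05)
  }
  g <- xpci:::gauss_blur(matrix(rnorm(256^2), 256), 2)
  expect_equal(autocorr_fwhm(g), autocorr_fwhm(50 + 3 * g), tolerance = 1e-9)
  # unit conversion of the speckle figure
  expect_equal(px_to_um(5.82, 1.28), 7.45, tolerance = 1e-3)
})

test_that("Fourier-spectrum resolution finds a planted band limit", {
  set.seed(2)
  n <- 256
  f0 <- 0.15   # cycles/px
  fy <- xpci:::fft_freq(n); fx <- xpci:::fft_freq(n)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  spec <- matrix(0, n, n)
  spec[fr <= f0] <- 1
  base <- Re(xpci:::ifft2(xpci:::fft2(matrix(rnorm(n^2), n)) * spec))
  base <- base / stats::sd(base)
  # carve a smooth signal-free pocket for the noise ROI (a sharp hole would
  # leak signal power across the spectrum)
  ii <- seq_len(n)
  win_1d <- function(c0, w, taper) {
    d <- pmax(abs(ii - c0) - w / 2, 0)
    0.5 - 0.5 * cos(pi * pmin(d / taper, 1))
  }
  window <- outer(win_1d(30, 48, 24), win_1d(30, 48, 24), pmax)
  # moderate SNR, as in a real reconstruction: strong out-of-band signal
  # would put windowing leakage above the noise floor
  slice <- base * window + matrix(rnorm(n^2, 0, 0.35), n)
  roi <- roi_spec(c(11, 11), c(40, 40), "background")
  res <- fourier_resolution(slice, roi, pixel_um = 1.28, n_bins = 96)
  expect_false(attr(res, "noise_limited"))
  expect_lt(abs(res - 1.28 / f0) / (1.28 / f0), 0.10)
})

test_that("resolution degrades monotonically with added noise and flags
           pure noise", {
  set.seed(3)
  n <- 192
  base <- xpci:::gauss_blur(matrix(rnorm(n^2), n), 2)
  base <- base / stats::sd(base)
  roi <- roi_spec(c(5, 5), c(40, 40), "background")
  res_at <- function(sigma) {
    noise <- matrix(rnorm(n^2, 0, sigma), n)
    sl <- base + noise
    sl[5:44, 5:44] <- noise[5:44, 5:44]
    as.numeric(fourier_resolution(sl, roi, 1.28))
  }
  r <- vapply(c(0.05, 0.15, 0.45), res_at, numeric(1))
  expect_true(all(diff(r) >= -1e-9))
  wn <- matrix(rnorm(n^2), n)
  res <- fourier_resolution(wn, roi, 1.28)
  expect_true(attr(res, "noise_limited"))
  expect_equal(as.numeric(res), 2 * 1.28)
})

test_that("angular sensitivity recovers a planted noise level at 40x40", {
  set.seed(4)
  sig <- 300e-9
  al <- list(alpha_x = matrix(rnorm(100^2, 0, sig), 100),
             alpha_y = matrix(rnorm(100^2, 0, 2 * sig), 100))
  roi <- roi_spec(c(30, 30), c(40, 40), "background")
  s <- angular_sensitivity(al, roi)
  expect_lt(abs(s[["sigma_x_nrad"]] - 300) / 300, 0.05)
  expect_lt(abs(s[["sigma_y_nrad"]] - 600) / 600, 0.05)
  expect_equal(mean(s), unname((s[1] + s[2]) / 2))
  # constant maps give zero
  al0 <- list(alpha_x = matrix(1e-7, 100, 100), alpha_y = matrix(0, 100, 100))
  expect_equal(unname(angular_sensitivity(al0, roi)), c(0, 0))
  # ROI overlapping the sample mask is rejected
  mask <- matrix(FALSE, 100, 100); mask[45, 45] <- TRUE
  expect_error(angular_sensitivity(al, roi, sample_mask = mask), "overlaps")
})

test_that("phase sensitivity recovers planted noise and ignores offsets", {
  set.seed(5)
  vol <- array(0.31 + rnorm(20 * 40 * 40, 0, 0.002), c(20, 40, 40))
  roi <- roi_spec(c(1, 1), c(40, 40), "background")
  s <- phase_sensitivity(vol, roi)
  expect_lt(abs(s - 0.002) / 0.002, 0.05)
  expect_equal(phase_sensitivity(vol + 5, roi), s)
  expect_equal(phase_sensitivity(array(1, c(4, 40, 40)), roi), 0)
  expect_warning(phase_sensitivity(matrix(rnorm(100), 10),
                                   roi_spec(c(1, 1), c(10, 10))), "1000")
})

test_that("CNR follows its defining arithmetic and recovers planted values", {
  sl <- matrix(4, 100, 100)
  sl[10:49, 10:49] <- 10
  sl[60:99, 60:99] <- 4 + rep(c(-2, 2), 800)   # sd = 2
  sig <- roi_spec(c(10, 10), c(40, 40), "signal")
  bg <- roi_spec(c(60, 60), c(40, 40), "background")
  expect_equal(cnr(sl, sig, bg), 6 / 2.0006254, tolerance = 1e-3)
  expect_error(cnr(sl, sig, roi_spec(c(30, 30), c(40, 40))), "disjoint")
  expect_error(cnr(matrix(1, 100, 100), sig, bg), "zero standard")
  # Monte-Carlo: planted CNR recovered within 10% on average
  set.seed(6)
  planted <- 5
  vals <- vapply(1:100, function(i) {
    m <- matrix(rnorm(100^2, 0, 1), 100)
    m[10:49, 10:49] <- m[10:49, 10:49] + planted
    cnr(m, sig, bg)
  }, numeric(1))
  expect_lt(abs(mean(vals) - planted) / planted, 0.10)
  expect_lt(stats::sd(vals) / planted, 0.15)
})

test_that("metrics report assembles units consistently", {
  r <- metrics_report("arm", mean_visibility = 0.2, autocorr_fwhm_px = 5.82,
                      resolution_um = 8, sigma_rho_e = 0.002,
                      cnr_mean = 6, cnr_sd = 1, pixel_um = 1.28)
  expect_equal(r$autocorr_fwhm_um, 7.4496)
  expect_equal(nrow(r), 1)
  expect_true(is.na(metrics_report("x")$resolution_um))
})
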