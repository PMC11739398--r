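# Quantitative image-quality metrics: modulator visibility and speckle
# size, Fourier-spectrum spatial resolution, angular sensitivity, phase
# sensitivity and contrast-to-noise ratio.

#' Region-of-interest specification
#'
#' @param origin_px `c(row, col)` of the ROI's upper-left pixel (1-based).
#' @param size_px `c(rows, cols)`; the conventional size for image-quality
#'   ROIs is 40 x 40 px.
#' @param role `"signal"` or `"background"`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(origin_px, size_px = c(40, 40),
                     role = c("signal", "background")) {
  structure(list(origin_px = as.integer(origin_px),
                 size_px = as.integer(size_px), role = match.arg(role)),
            class = "roi_spec")
}

# extract ROI values from a matrix (or a [slice, y, x] array slice-wise)
roi_values <- function(img, roi) {
  r <- roi$origin_px[1] + seq_len(roi$size_px[1]) - 1
  c_ <- roi$origin_px[2] + seq_len(roi$size_px[2]) - 1
  check_that(min(r) >= 1 && max(r) <= nrow(img) &&
               min(c_) >= 1 && max(c_) <= ncol(img),
             "ROI out of image bounds")
  img[r, c_]
}

#' Per-pixel visibility map of a reference pattern
#'
#' Visibility is the local standard deviation over the local mean of the
#' reference image, for each pixel (population standard deviation over a
#' sliding window).
#'
#' @param reference_image positive image.
#' @param window_px sliding window size (odd, >= 3; default 15 px, about two
#'   TAI periods at 1.28 micron pixels).
#' @return object of class `visibility_map`: list with `values`,
#'   `window_px`, `mean_visibility`.
#' @export
visibility_map <- function(reference_image, window_px = 15) {
  check_that(window_px >= 3, "window must be >= 3 px")
  check_that(all(reference_image > 0), "reference image must be positive")
  h <- (as.integer(window_px) - 1L) %/% 2L
  n <- win_count(nrow(reference_image), ncol(reference_image), h)
  s1 <- win_sum(reference_image, h)
  s2 <- win_sum(reference_image^2, h)
  mu <- s1 / n
  varp <- pmax(s2 / n - mu^2, 0)
  v <- sqrt(varp) / mu
  structure(list(values = v, window_px = window_px,
                 mean_visibility = mean(v)),
            class = "visibility_map")
}

#' Speckle / marking-structure size from the pattern autocorrelation
#'
#' Full width at half maximum of the central peak of the mean-subtracted,
#' normalised 2D autocorrelation of the pattern, measured along both axes
#' through the peak (sub-pixel by linear interpolation of the half-maximum
#' crossings) and averaged.
#'
#' @param reference_image the pattern.
#' @return FWHM in px.
#' @export
autocorr_fwhm <- function(reference_image) {
  m <- reference_image - mean(reference_image)
  F <- fft2(m)
  ac <- Re(ifft2(F * Conj(F)))
  ac <- ac / ac[1, 1]
  nr <- nrow(ac); nc <- ncol(ac)
  # profiles through the zero-lag peak, lags -n/2..n/2
  half_width <- function(prof) {
    # prof[1] is lag 0 (=1); walk outward to the first crossing of 0.5
    n <- length(prof)
    below <- which(prof < 0.5)
    if (length(below) == 0)
      stop("autocorrelation peak not resolved (no half-maximum crossing)")
    i <- below[1]
    if (i == 1) return(0.5)  # sampling-limited
    # linear interpolation between lag i-2 and i-1
    p0 <- prof[i - 1]; p1 <- prof[i]
    (i - 2) + (p0 - 0.5) / (p0 - p1)
  }
  wy <- half_width(ac[seq_len(floor(nr / 2)), 1]) +
    half_width(ac[c(1, nr:(nr - floor(nr / 2) + 2)), 1])
  wx <- half_width(ac[1, seq_len(floor(nc / 2))]) +
    half_width(ac[1, c(1, nc:(nc - floor(nc / 2) + 2))])
  (wy + wx) / 2
}

#' Spatial resolution from the Fourier power spectrum
#'
#' Azimuthally averaged power spectrum of the slice compared against the
#' flat noise floor predicted (via Parseval) from the variance of a
#' homogeneous noise ROI; the resolution is `1 / f_c` where the spectrum
#' first falls to the floor, located by log-domain linear interpolation.
#'
#' @param volume_slice 2D slice.
#' @param noise_roi a [roi_spec()] in a homogeneous region of the slice.
#' @param pixel_um pixel size (microns).
#' @param n_bins number of radial frequency bins.
#' @return resolution in microns; attribute `noise_limited` is `TRUE` when
#'   the spectrum never reaches the floor and the Nyquist-limited bound is
#'   returned.
#' @export
fourier_resolution <- function(volume_slice, noise_roi, pixel_um,
                               n_bins = 64) {
  vals <- roi_values(volume_slice, noise_roi)
  # split-half stationarity check of the noise ROI
  v1 <- stats::var(as.vector(vals[, seq_len(floor(ncol(vals) / 2))]))
  v2 <- stats::var(as.vector(vals[, -seq_len(floor(ncol(vals) / 2))]))
  if (max(v1, v2) / max(min(v1, v2), 1e-300) > 25)
    warning("noise ROI variance not stationary; resolution may be biased")
  sigma2 <- stats::var(as.vector(vals))
  nr <- nrow(volume_slice); nc <- ncol(volume_slice)
  # for white noise of variance sigma2, E|F|^2 = N * sigma2 (Parseval)
  floor_power <- nr * nc * sigma2
  F <- fft2(volume_slice - mean(volume_slice))
  P <- Re(F * Conj(F))
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  nyq <- 0.5
  bins <- seq(0, nyq, length.out = n_bins + 1)
  bi <- pmin(findInterval(fr, bins, rightmost.closed = TRUE), n_bins)
  keep <- fr > 0 & fr <= nyq
  spec <- tapply(P[keep], bi[keep], mean)
  fmid <- (bins[-1] + bins[-length(bins)]) / 2
  fmid <- fmid[as.integer(names(spec))]
  # the ROI floor estimate carries sampling error, so the crossing is
  # detected with a 20% tolerance band around the predicted floor
  below <- which(spec <= 1.2 * floor_power)
  noise_limited <- length(below) == 0 || below[1] == 1 ||
    stats::median(spec[seq_len(min(4, length(spec)))]) <= 2 * floor_power
  if (noise_limited) {
    res <- 2 * pixel_um  # Nyquist-limited bound
    attr(res, "noise_limited") <- TRUE
    return(res)
  }
  i <- below[1]
  l0 <- log(spec[i - 1]); l1 <- log(pmax(spec[i], 1e-300))
  lf <- log(1.2 * floor_power)
  fc <- fmid[i - 1] + (l0 - lf) / (l0 - l1) * (fmid[i] - fmid[i - 1])
  res <- pixel_um / fc
  attr(res, "noise_limited") <- FALSE
  res
}

#' Angular sensitivity of the refraction-angle maps
#'
#' Standard deviation over a homogeneous, sample-free background ROI of the
#' horizontal and vertical refraction-angle images, in nrad.
#'
#' @param alpha_maps a [displacements_to_angles()] result.
#' @param background_roi a [roi_spec()] outside the sample support.
#' @param sample_mask optional logical matrix of sample pixels; the ROI must
#'   not overlap it.
#' @return named vector `c(sigma_x_nrad, sigma_y_nrad)`.
#' @export
angular_sensitivity <- function(alpha_maps, background_roi,
                                sample_mask = NULL) {
  if (!is.null(sample_mask) && any(roi_values(sample_mask, background_roi)))
    stop("background ROI overlaps the sample mask")
  c(sigma_x_nrad = stats::sd(roi_values(alpha_maps$alpha_x, background_roi)) * 1e9,
    sigma_y_nrad = stats::sd(roi_values(alpha_maps$alpha_y, background_roi)) * 1e9)
}

#' Phase sensitivity (electron-density noise)
#'
#' Standard deviation of the electron density over a homogeneous ROI, in
#' electrons per cubic angstrom: the smallest resolvable density
#' difference.
#'
#' @param rho_e_volume an [delta_to_electron_density()] result, or a bare
#'   array/matrix of electron densities.
#' @param homogeneous_roi a [roi_spec()] (applied slice-wise to 3D input).
#' @return sigma_rho_e in electrons/A^3.
#' @export
phase_sensitivity <- function(rho_e_volume, homogeneous_roi) {
  vals <- if (inherits(rho_e_volume, "electron_density_volume"))
    rho_e_volume$rho_e else rho_e_volume
  get_vals <- function(m) roi_values(m, homogeneous_roi)
  v <- if (is.matrix(vals)) get_vals(vals)
  else unlist(lapply(seq_len(dim(vals)[1]), function(i) get_vals(vals[i, , ])))
  if (length(v) < 1000)
    warning("homogeneous ROI has fewer than 1000 voxels; estimate is noisy")
  stats::sd(v)
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = |I_s - I_b| / sigma_b` with ROI means `I_s`, `I_b` and background
#' standard deviation `sigma_b`.
#'
#' @param slice 2D image.
#' @param signal_roi,background_roi disjoint [roi_spec()]s.
#' @return CNR value.
#' @export
cnr <- function(slice, signal_roi, background_roi) {
  r1 <- signal_roi$origin_px; r2 <- background_roi$origin_px
  s1 <- signal_roi$size_px; s2 <- background_roi$size_px
  overlap <- r1[1] < r2[1] + s2[1] && r2[1] < r1[1] + s1[1] &&
    r1[2] < r2[2] + s2[2] && r2[2] < r1[2] + s1[2]
  check_that(!overlap, "signal and background ROIs must be disjoint")
  sv <- roi_values(slice, signal_roi)
  bv <- roi_values(slice, background_roi)
  sb <- stats::sd(bv)
  if (sb == 0) stop("background ROI has zero standard deviation")
  abs(mean(sv) - mean(bv)) / sb
}

#' Assemble a metrics report row
#'
#' Bundles the metric suite into a one-row data frame, the package's
#' counterpart of a per-dataset image-quality table.
#'
#' @param method dataset label.
#' @param mean_visibility,autocorr_fwhm_px,resolution_um numeric summaries.
#' @param sigma_alpha_x_nrad,sigma_alpha_y_nrad,sigma_rho_e,cnr_mean,cnr_sd
#'   numeric summaries (use `NA` where a metric does not apply).
#' @param pixel_um pixel size used for unit conversions.
#' @return one-row data frame with an `autocorr_fwhm_um` column derived via
#'   [px_to_um()].
#' @export
metrics_report <- function(method, mean_visibility = NA, autocorr_fwhm_px = NA,
                           resolution_um = NA, sigma_alpha_x_nrad = NA,
                           sigma_alpha_y_nrad = NA, sigma_rho_e = NA,
                           cnr_mean = NA, cnr_sd = NA, pixel_um = 1.28) {
  data.frame(method = method, mean_visibility = mean_visibility,
             autocorr_fwhm_px = autocorr_fwhm_px,
             autocorr_fwhm_um = ifelse(is.na(autocorr_fwhm_px), NA,
                                       px_to_um(autocorr_fwhm_px, pixel_um)),
             resolution_um = as.numeric(resolution_um),
             sigma_alpha_x_nrad = sigma_alpha_x_nrad,
             sigma_alpha_y_nrad = sigma_alpha_y_nrad,
             sigma_rho_e = sigma_rho_e, cnr_mean = cnr_mean, cnr_sd = cnr_sd,
             stringsAsFactors = FALSE)
}
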