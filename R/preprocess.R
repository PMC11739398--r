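# Raw-frame conditioning: dark/flat correction, bad-pixel repair,
# beam-profile estimation and modulator drift correction.

#' Correction configuration
#'
#' @param badpixel_sigma outlier threshold in robust sigma units.
#' @param beamprofile_kernel_px low-pass kernel size for the beam profile
#'   (rounded to the next odd integer, >= 3).
#' @param drift_correction logical.
#' @param drift_upsample sub-pixel registration upsampling factor.
#' @return object of class `correction_config`.
#' @export
correction_config <- function(badpixel_sigma = 6, beamprofile_kernel_px = 50,
                              drift_correction = TRUE, drift_upsample = 20) {
  k <- as.integer(round(beamprofile_kernel_px))
  if (k %% 2 == 0) k <- k + 1L
  check_that(k >= 3, "beamprofile kernel must round to >= 3")
  check_that(badpixel_sigma > 0, "badpixel_sigma must be > 0")
  structure(list(badpixel_sigma = badpixel_sigma, beamprofile_kernel_px = k,
                 drift_correction = drift_correction,
                 drift_upsample = drift_upsample),
            class = "correction_config")
}

#' Dark and flat-field correction
#'
#' `(raw - dark_mean) / (flat_mean - dark_mean)`. Pixels where the
#' denominator is not positive are flagged (set to `NA`) for subsequent
#' repair by [replace_bad_pixels()]; if they exceed 5% of the frame an error
#' is raised.
#'
#' @param raw raw frame.
#' @param dark_mean mean dark frame.
#' @param flat_mean mean flat (open-beam) frame.
#' @return corrected frame with invalid pixels set to `NA`.
#' @export
correct_dark_flat <- function(raw, dark_mean, flat_mean) {
  check_that(all(dim(raw) == dim(dark_mean)) && all(dim(raw) == dim(flat_mean)),
             "frame shapes must match")
  den <- flat_mean - dark_mean
  bad <- !(den > 0)
  if (mean(bad) > 0.05)
    stop(sprintf("non-positive flat-dark denominator on %.1f%% of the frame",
                 100 * mean(bad)))
  out <- (raw - dark_mean) / den
  out[bad] <- NA_real_
  out
}

# 8-neighbour shifted copies of a matrix with replicated edges
.neighbour_stack <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- c(1L, seq_len(nr - 1)); dn <- c(seq_len(nr - 1) + 1L, nr)
  lf <- c(1L, seq_len(nc - 1)); rt <- c(seq_len(nc - 1) + 1L, nc)
  list(img[up, lf], img[up, ], img[up, rt],
       img[, lf],             img[, rt],
       img[dn, lf], img[dn, ], img[dn, rt])
}

#' Replace bad pixels by the median of their neighbours
#'
#' Pixels deviating from the median of their 8 closest neighbours by more
#' than `badpixel_sigma` robust standard deviations (1.4826 * MAD of the
#' deviation image), and all non-finite pixels, are replaced by the
#' neighbour median (valid neighbours only; ties resolve to the lower
#' value). All other pixels are returned bit-identical.
#'
#' @param image input frame (may contain `NA`s flagged upstream).
#' @param badpixel_sigma threshold in robust sigma units.
#' @return repaired frame; attribute `n_replaced` carries the count.
#' @export
replace_bad_pixels <- function(image, badpixel_sigma = 6) {
  nb <- .neighbour_stack(image)
  valid <- lapply(nb, function(m) is.finite(m))
  # neighbour median ignoring NA: replace NA by +Inf for lower-median order
  # statistic among valid values
  nb_inf <- lapply(nb, function(m) { m[!is.finite(m)] <- Inf; m })
  n <- length(nb_inf)
  mats <- nb_inf
  for (i in seq_len(n - 1)) for (j in seq_len(n - i)) {
    a <- mats[[j]]; b <- mats[[j + 1]]
    mats[[j]] <- pmin(a, b); mats[[j + 1]] <- pmax(a, b)
  }
  nv <- Reduce(`+`, valid)                       # valid neighbour count
  kth <- pmax(1L, (nv + 1L) %/% 2L)              # lower median rank
  nr <- nrow(image); nc <- ncol(image)
  med <- matrix(NA_real_, nr, nc)
  for (k in sort(unique(as.integer(kth)))) {
    sel <- kth == k
    med[sel] <- mats[[k]][sel]
  }
  med[nv == 0] <- NA_real_
  dev <- image - med
  sigma <- 1.4826 * stats::median(abs(dev), na.rm = TRUE)
  bad <- !is.finite(image) | (is.finite(dev) & abs(dev) > badpixel_sigma * pmax(sigma, .Machine$double.eps))
  if (mean(bad) > 0.10)
    stop(sprintf("%.1f%% pixels flagged as bad; check dark/flat frames",
                 100 * mean(bad)))
  out <- image
  out[bad] <- med[bad]
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Estimate the smooth beam profile from reference frames
#'
#' Mean of the frames followed by a boxcar low pass of the stated kernel
#' size. A kernel at least as large as the image returns the global mean.
#'
#' @param reference_frames a matrix, a list of matrices, or a 3D array
#'   `[frame, rows, cols]`.
#' @param kernel_px low-pass kernel size in px (default 50).
#' @return strictly positive profile image.
#' @export
estimate_beam_profile <- function(reference_frames, kernel_px = 50) {
  frames <- if (is.matrix(reference_frames)) list(reference_frames)
  else if (is.array(reference_frames) && length(dim(reference_frames)) == 3)
    lapply(seq_len(dim(reference_frames)[1]),
           function(i) reference_frames[i, , ])
  else reference_frames
  check_that(length(frames) >= 1, "need at least one reference frame")
  m <- Reduce(`+`, frames) / length(frames)
  k <- as.integer(round(kernel_px)); if (k %% 2 == 0) k <- k + 1L
  k <- max(k, 3L)
  profile <- if (k >= max(dim(m))) matrix(mean(m), nrow(m), ncol(m))
             else box_blur(m, k)
  if (any(profile <= 0))
    stop("beam profile has non-positive pixels; check the reference frames")
  profile
}

# Phase-correlation rigid shift estimate with sub-pixel refinement by a
# matrix-multiply DFT around the coarse peak (cross-correlation upsampling).
.register_shift <- function(a, b, upsample = 20) {
  nr <- nrow(a); nc <- ncol(a)
  A <- fft2(a - mean(a)); B <- fft2(b - mean(b))
  CP <- A * Conj(B)
  cc <- Re(ifft2(CP))
  pk <- which.max(cc)
  py <- (pk - 1) %% nr; px <- (pk - 1) %/% nr
  if (py > nr / 2) py <- py - nr
  if (px > nc / 2) px <- px - nc
  peak_ratio <- max(cc) / max(1e-30, stats::sd(cc))
  # refine on a 1.5 px neighbourhood at 1/upsample resolution
  if (upsample > 1) {
    fy <- fft_freq(nr); fx <- fft_freq(nc)
    dy <- py + seq(-0.75, 0.75, by = 1 / upsample)
    dx <- px + seq(-0.75, 0.75, by = 1 / upsample)
    Ey <- exp(2i * pi * outer(dy, fy))        # n_dy x nr
    Ex <- exp(2i * pi * outer(fx, dx))        # nc x n_dx
    local <- Re(Ey %*% CP %*% Ex) / (nr * nc)
    ij <- which(local == max(local), arr.ind = TRUE)[1, ]
    py <- dy[ij[1]]; px <- dx[ij[2]]
  }
  list(shift = c(py, px), peak_ratio = peak_ratio)
}

#' Modulator drift correction
#'
#' Estimates the rigid transverse shift between the current sample-frame
#' pattern and the stored reference pattern by cross-correlation with
#' sub-pixel (upsampled) peak localisation, and returns the reference
#' resampled by that shift. If the correlation peak is too weak a warning is
#' raised and the unshifted reference returned.
#'
#' @param sample_frame frame whose pattern position is to be matched.
#' @param reference_frames_for_step reference frame (matrix), list of frames
#'   or `[frame, rows, cols]` array for the current modulator step (averaged
#'   before registration).
#' @param upsample sub-pixel refinement factor (shift resolved to
#'   `1/upsample` px).
#' @param region optional list `list(rows =, cols =)` restricting
#'   registration to a sample-free region.
#' @param min_peak_ratio minimum correlation peak / sd ratio before warning.
#' @return list with `matched_reference` and `shift_px` (`c(dy, dx)`: the
#'   displacement of the sample pattern relative to the reference).
#' @export
correct_drift <- function(sample_frame, reference_frames_for_step,
                          upsample = 20, region = NULL, min_peak_ratio = 5) {
  ref <- if (is.matrix(reference_frames_for_step)) reference_frames_for_step
  else if (is.array(reference_frames_for_step) &&
           length(dim(reference_frames_for_step)) == 3)
    apply(reference_frames_for_step, c(2, 3), mean)
  else Reduce(`+`, reference_frames_for_step) / length(reference_frames_for_step)
  a <- sample_frame; b <- ref
  if (!is.null(region)) { a <- a[region$rows, region$cols]
                          b <- b[region$rows, region$cols] }
  est <- .register_shift(a, b, upsample)
  if (est$peak_ratio < min_peak_ratio) {
    warning("drift correlation peak too weak; returning unshifted reference")
    return(list(matched_reference = ref, shift_px = c(0, 0)))
  }
  list(matched_reference = fourier_shift(ref, est$shift[1], est$shift[2]),
       shift_px = est$shift)
}
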