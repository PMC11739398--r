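# From differential phase to absolute phase: background detrending, Fourier
# (Frankot-Chellappa-type) least-squares integration, residual polynomial
# removal.

#' Gradient field container
#'
#' @param gx,gy dPhi/dx and dPhi/dy maps (rad/m); x = columns, y = rows.
#' @param pixel_um sampling pitch (microns).
#' @return object of class `gradient_field`.
#' @export
gradient_field <- function(gx, gy, pixel_um) {
  check_that(all(dim(gx) == dim(gy)), "gx and gy shapes differ")
  check_that(all(is.finite(gx)) && all(is.finite(gy)),
             "gradients must be finite")
  structure(list(gx = gx, gy = gy, pixel_um = pixel_um),
            class = "gradient_field")
}

#' Phase projection container
#'
#' @param phi integrated phase (rad).
#' @param pixel_um sampling pitch (microns).
#' @param background_mask logical matrix of sample-free pixels (or `NULL`).
#' @return object of class `phase_projection`.
#' @export
phase_projection <- function(phi, pixel_um, background_mask = NULL) {
  structure(list(phi = phi, pixel_um = pixel_um,
                 background_mask = background_mask),
            class = "phase_projection")
}

#' Border background mask
#'
#' Default "background areas" when none are supplied: a frame border of the
#' given width. For samples that fill the field of view vertically (the
#' usual tomographic geometry, where the specimen column crosses the whole
#' frame height), use `sides = "cols"` to restrict the background to the
#' left/right margins.
#'
#' @param shape `c(rows, cols)`.
#' @param border_px border width in px.
#' @param sides `"all"` (full frame border) or `"cols"` (left/right margins
#'   only).
#' @return logical matrix.
#' @export
border_mask <- function(shape, border_px = 32, sides = c("all", "cols")) {
  sides <- match.arg(sides)
  m <- matrix(FALSE, shape[1], shape[2])
  b <- min(border_px, floor(min(shape) / 2))
  if (sides == "all")
    m[c(seq_len(b), shape[1] - seq_len(b) + 1), ] <- TRUE
  m[, c(seq_len(b), shape[2] - seq_len(b) + 1)] <- TRUE
  m
}

# least-squares 2D polynomial fit on masked pixels; returns fitted surface
.poly_fit_surface <- function(img, mask, order) {
  nr <- nrow(img); nc <- ncol(img)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) / nc - 0.5
  y <- matrix(seq_len(nr), nr, nc) / nr - 0.5
  terms <- list(matrix(1, nr, nc), x, y)
  if (order >= 2) terms <- c(terms, list(x * x, x * y, y * y))
  X <- vapply(terms, function(t) t[mask], numeric(sum(mask)))
  if (qr(X)$rank < ncol(X))
    stop("background mask geometry is degenerate (collinear); enlarge it")
  beta <- qr.solve(X, img[mask])
  fit <- matrix(0, nr, nc)
  for (i in seq_along(terms)) fit <- fit + beta[i] * terms[[i]]
  fit
}

#' Detrend differential-phase channels
#'
#' Fits a first-order 2D polynomial (plane) to the background pixels of each
#' channel and subtracts it everywhere, removing slow instrumental phase
#' ramps before integration.
#'
#' @param gradient_f a [gradient_field()].
#' @param background_mask logical matrix of sample-free pixels.
#' @return detrended [gradient_field()].
#' @export
detrend_dpc <- function(gradient_f, background_mask) {
  check_that(any(background_mask), "background mask is empty")
  if (sum(background_mask) < 100)
    warning("background mask has fewer than 100 px; detrend may be unstable")
  gx <- gradient_f$gx - .poly_fit_surface(gradient_f$gx, background_mask, 1)
  gy <- gradient_f$gy - .poly_fit_surface(gradient_f$gy, background_mask, 1)
  gradient_field(gx, gy, gradient_f$pixel_um)
}

#' Fourier-space least-squares integration of a gradient field
#'
#' Least-squares solution of `grad Phi = (gx, gy)` in Fourier space:
#' `Phi_hat(f) = -i (fx gx_hat + fy gy_hat) / (2 pi (fx^2 + fy^2))` with the
#' DC term set to zero. The field is mirror-padded (even in the transverse
#' direction, odd along the differentiated direction) before the transform
#' to suppress wrap-around.
#'
#' @param gradient_f a [gradient_field()] (detrending recommended first).
#' @param pad logical; mirror-pad before the FFT (default `TRUE`).
#' @return a [phase_projection()] with `phi` in rad (additive constant fixed
#'   by a zero DC term).
#' @export
fourier_integrate <- function(gradient_f, pad = TRUE) {
  gx <- gradient_f$gx; gy <- gradient_f$gy
  d_m <- gradient_f$pixel_um * 1e-6
  if (pad) {
    # gradient of an even extension of Phi: gx is odd in x / even in y,
    # gy is odd in y / even in x
    fx_ext <- function(m) cbind(m, -m[, rev(seq_len(ncol(m))), drop = FALSE])
    fy_ext <- function(m) rbind(m, -m[rev(seq_len(nrow(m))), , drop = FALSE])
    ex_ext <- function(m) cbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
    ey_ext <- function(m) rbind(m, m[rev(seq_len(nrow(m))), , drop = FALSE])
    gx <- ey_ext(fx_ext(gx))
    gy <- fy_ext(ex_ext(gy))
  }
  nr <- nrow(gx); nc <- ncol(gx)
  fy <- fft_freq(nr, d_m); fx <- fft_freq(nc, d_m)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  den <- 2 * pi * (FX^2 + FY^2)
  num <- -1i * (FX * fft2(gx) + FY * fft2(gy))
  den[1, 1] <- 1; num[1, 1] <- 0
  phi <- Re(ifft2(num / den))
  if (pad) phi <- phi[seq_len(nr / 2), seq_len(nc / 2)]
  phase_projection(phi, gradient_f$pixel_um)
}

#' Remove residual low-order trends from an integrated phase map
#'
#' Fits a second-order 2D polynomial to the background pixels and subtracts
#' it everywhere, suppressing residual low frequencies left by the
#' integration.
#'
#' @param phase_proj a [phase_projection()].
#' @param background_mask logical matrix; defaults to the mask stored in the
#'   projection.
#' @return detrended [phase_projection()].
#' @export
detrend_phase <- function(phase_proj, background_mask = NULL) {
  mask <- background_mask %||% phase_proj$background_mask
  check_that(!is.null(mask) && any(mask), "background mask required")
  if (sum(mask) < 100)
    warning("background mask has fewer than 100 px; detrend may be unstable")
  phi <- phase_proj$phi - .poly_fit_surface(phase_proj$phi, mask, 2)
  phase_projection(phi, phase_proj$pixel_um, mask)
}
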