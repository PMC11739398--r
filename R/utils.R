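# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrete Fourier transform sample frequencies
#'
#' Frequencies (cycles per unit of `d`) in standard FFT order, as returned by
#' [stats::fft()].
#'
#' @param n number of samples.
#' @param d sample spacing (default 1, giving cycles/sample).
#' @return numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Integer circular shift of a matrix: content moves down by dy rows and right
# by dx columns.
shift_int <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  img[ri, ci, drop = FALSE]
}

# Sub-pixel shift via Fourier phase ramp (periodic boundary). Content moves by
# (dy, dx); exact for band-limited data.
fourier_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  fy <- fft_freq(nr); fx <- fft_freq(nc)
  ramp <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  # suppress the unmatched Nyquist bin for non-integer shifts to keep output real
  if (nr %% 2 == 0 && abs(dy - round(dy)) > 1e-12) ramp[nr / 2 + 1, ] <- 0
  if (nc %% 2 == 0 && abs(dx - round(dx)) > 1e-12) ramp[, nc / 2 + 1] <- 0
  Re(ifft2(fft2(img) * ramp))
}

# Bilinear sub-pixel shift with replicated edges. Content moves by (dy, dx).
bilinear_shift <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  y <- pmin(pmax(seq_len(nr) - dy, 1), nr)
  x <- pmin(pmax(seq_len(nc) - dx, 1), nc)
  y0 <- pmin(floor(y), nr - 1); x0 <- pmin(floor(x), nc - 1)
  wy <- y - y0; wx <- x - x0
  a <- img[y0, x0, drop = FALSE]; b <- img[y0, x0 + 1, drop = FALSE]
  c_ <- img[y0 + 1, x0, drop = FALSE]; d <- img[y0 + 1, x0 + 1, drop = FALSE]
  WY <- matrix(wy, nr, nc); WX <- matrix(wx, nr, nc, byrow = TRUE)
  (1 - WY) * ((1 - WX) * a + WX * b) + WY * ((1 - WX) * c_ + WX * d)
}

# Windowed (box) sum over a (2h+1)^2 neighbourhood via an integral image.
# Windows are truncated at the borders (sum over in-bounds pixels only).
win_sum <- function(img, h) {
  if (h == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  # column-wise running sums from one full-vector cumsum (column-major),
  # correcting each column by the total of the preceding columns
  cs <- matrix(cumsum(img), nr, nc)
  if (nc > 1) cs <- cs - matrix(rep(c(0, cs[nr, -nc]), each = nr), nr, nc)
  cst <- t(cs)
  cs2 <- matrix(cumsum(cst), nc, nr)
  if (nr > 1) cs2 <- cs2 - matrix(rep(c(0, cs2[nc, -nr]), each = nc), nc, nr)
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- t(cs2)
  # prefix indices: window rows max(i-h, 1)..min(i+h, nr), S[j+1] = rows 1..j
  r1 <- pmax(seq_len(nr) - h - 1, 0); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h - 1, 0); c2 <- pmin(seq_len(nc) + h, nc)
  S[r2 + 1, c2 + 1] - S[r1 + 1, c2 + 1] - S[r2 + 1, c1 + 1] + S[r1 + 1, c1 + 1]
}

# Per-pixel count of in-bounds window pixels matching win_sum truncation.
win_count <- function(nr, nc, h) {
  ry <- pmin(seq_len(nr) + h, nr) - pmax(seq_len(nr) - h - 1, 0)
  rx <- pmin(seq_len(nc) + h, nc) - pmax(seq_len(nc) - h - 1, 0)
  outer(ry, rx)
}

# Separable boxcar mean with replicate padding (kernel size k, odd).
box_blur <- function(img, k) {
  k <- as.integer(k)
  if (k %% 2 == 0) k <- k + 1L
  if (k <= 1) return(img)
  h <- (k - 1L) %/% 2L
  pad_blur_1d <- function(m, h) {
    n <- nrow(m)
    p <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(n, h), , drop = FALSE])
    cs <- rbind(0, apply(p, 2, cumsum))
    (cs[(2 * h + 2):(n + 2 * h + 1), , drop = FALSE] - cs[1:n, , drop = FALSE]) / (2 * h + 1)
  }
  t(pad_blur_1d(t(pad_blur_1d(img, h)), h))
}

# Separable Gaussian blur with replicate padding; sigma in pixels.
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2)); g <- g / sum(g)
  conv_1d <- function(m) {
    n <- nrow(m)
    p <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(g)) out <- out + g[i] * p[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(conv_1d(t(conv_1d(img))))
}

# Lower-median across the columns of a small stack of matrices (list of equal
# matrices): the floor((n+1)/2)-th order statistic, so ties/even counts resolve
# to the lower value. Uses pairwise min/max exchange passes (fully vectorised).
lower_median_stack <- function(mats) {
  n <- length(mats)
  stopifnot(n >= 1)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(n - i)) {
      a <- mats[[j]]; b <- mats[[j + 1]]
      mats[[j]] <- pmin(a, b); mats[[j + 1]] <- pmax(a, b)
    }
  }
  mats[[(n + 1) %/% 2]]
}

# Even (mirror) extension of a matrix to (2 nr) x (2 nc).
mirror_pad_even <- function(m) {
  top <- cbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
  rbind(top, top[rev(seq_len(nrow(m))), , drop = FALSE])
}

# assertion helper with caller-readable message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
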