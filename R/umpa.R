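# Windowed modulated-pattern analysis (UMPA-style): per-pixel least-squares
# recovery of transmission T, pattern displacement (u_x, u_y) and dark-field
# D from stepped reference/sample frame stacks, and the conversion of
# displacements to refraction angles and differential phase.
#
# Model, for each pixel r and candidate displacement u:
#   I_sam,m(r) ~ T * [ Iref_bar(r-u) + D * (I_ref,m(r-u) - Iref_bar(r-u)) ]
# where Iref_bar is the reference mean over the modulator steps m. The
# residual is summed over the steps and a (2h+1)^2 window. Because
# sum_m (I_ref,m - Iref_bar) = 0 pointwise, the two regressors are
# orthogonal and T and D have closed-form optima for every candidate u.
# The returned u is the displacement of the sample pattern relative to the
# reference (the reference is sampled at r - u), so that
# alpha = u * pixel / z_eff points along the physical refraction direction
# of the simulator.

#' Matching configuration
#'
#' @param window_half_px analysis-window half-size h; the window is
#'   `(2h+1)^2` pixels (default h = 1, a 3x3 window).
#' @param search_radius_px integer search radius in px.
#' @param subpixel `"iterative"` (default: parabola start, then iterative
#'   warping refinement, which suppresses the pixel-locking bias of pure
#'   parabola interpolation), `"parabola"` (separable 3-point parabola
#'   refinement only) or `"refine_off"` (integer displacements).
#' @param estimate_darkfield logical; when `FALSE`, D is fixed to 1.
#' @param n_iter warping iterations for `subpixel = "iterative"`.
#' @return object of class `match_config`.
#' @export
match_config <- function(window_half_px = 1, search_radius_px = 2,
                         subpixel = c("iterative", "parabola", "refine_off"),
                         estimate_darkfield = TRUE, n_iter = 4) {
  check_that(window_half_px >= 0, "window_half_px must be >= 0")
  check_that(search_radius_px >= 1, "search_radius_px must be >= 1")
  structure(list(window_half_px = as.integer(window_half_px),
                 search_radius_px = as.integer(search_radius_px),
                 subpixel = match.arg(subpixel),
                 estimate_darkfield = isTRUE(estimate_darkfield),
                 n_iter = as.integer(n_iter)),
            class = "match_config")
}

# stack helpers: accept [step, rows, cols] arrays or lists of matrices
.as_stack <- function(x) {
  out <- if (is.list(x)) x
  else if (is.matrix(x)) list(x)
  else {
    check_that(length(dim(x)) == 3, "stack must be [step, rows, cols]")
    lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  }
  # integer frames (raw photon counts) would overflow in the product sums
  lapply(out, function(m) { storage.mode(m) <- "double"; m })
}

# one discrete matching pass: exhaustive integer search in [-sr, sr]^2 with
# closed-form T/D per candidate, optional separable parabola refinement.
.match_stage <- function(S, R, h, sr, darkfield, parabola) {
  M <- length(S)
  nr <- nrow(S[[1]]); nc <- ncol(S[[1]])
  eps <- .Machine$double.eps

  Ssum <- Reduce(`+`, S)
  S2 <- Reduce(`+`, lapply(S, function(m) m * m))
  s1 <- win_sum(S2, h)
  Rbar <- Reduce(`+`, R) / M
  R2 <- Reduce(`+`, lapply(R, function(m) m * m))

  shifts <- expand.grid(dy = -sr:sr, dx = -sr:sr)
  n_cand <- nrow(shifts)
  flat <- matrix(Inf, nr * nc, n_cand)
  Tcand <- vector("list", n_cand)
  Dcand <- vector("list", n_cand)

  for (ci in seq_len(n_cand)) {
    dy <- shifts$dy[ci]; dx <- shifts$dx[ci]
    # reference sampled at r - u <=> reference arrays shifted by +u
    A <- shift_int(Rbar, dy, dx)
    cross <- Reduce(`+`, lapply(seq_len(M), function(m)
      shift_int(R[[m]], dy, dx) * S[[m]]))
    if (darkfield) {
      R2s <- shift_int(R2, dy, dx)
      s2 <- win_sum(M * A * A, h)
      s3 <- win_sum(A * Ssum, h)
      s4 <- win_sum(R2s - M * A * A, h)
      s5 <- win_sum(cross - A * Ssum, h)
      degen <- is.na(s4) | s4 <= eps * pmax(s2, 1)
      c1 <- s3 / pmax(s2, eps)
      c2 <- s5 / pmax(s4, eps)
      c2[degen] <- c1[degen]
      cst <- s1 - c1 * s3 - c2 * s5
      cst[degen] <- (s1 - c1 * s3)[degen]
      Tcand[[ci]] <- c1
      D <- c2 / ifelse(abs(c1) < eps, eps, c1)
      D[degen] <- 1
      Dcand[[ci]] <- D
    } else {
      rr <- win_sum(shift_int(R2, dy, dx), h)
      rs <- win_sum(cross, h)
      cst <- s1 - rs * rs / pmax(rr, eps)
      Tcand[[ci]] <- rs / pmax(rr, eps)
      Dcand[[ci]] <- matrix(1, nr, nc)
    }
    cst[!is.finite(cst)] <- Inf
    flat[, ci] <- cst
  }

  best <- max.col(-flat, ties.method = "first")
  pix <- seq_len(nr * nc)
  u_y <- matrix(shifts$dy[best], nr, nc)
  u_x <- matrix(shifts$dx[best], nr, nc)
  Tm <- matrix(0, nr, nc); Dm <- matrix(1, nr, nc)
  resid <- matrix(flat[cbind(pix, best)], nr, nc)
  for (ci in unique(best)) {
    sel <- best == ci
    Tm[sel] <- Tcand[[ci]][sel]
    Dm[sel] <- Dcand[[ci]][sel]
  }

  if (parabola) {
    idx_of <- function(dy, dx) (dx + sr) * (2 * sr + 1) + (dy + sr) + 1
    by <- shifts$dy[best]; bx <- shifts$dx[best]
    c0 <- flat[cbind(pix, best)]
    # an (almost) exact discrete match needs no refinement; refining on a
    # numerically zero minimum only amplifies rounding noise
    ok0 <- c0 > 1e-9 * (s1[pix] + 1e-300)
    ok <- ok0 & abs(by) < sr
    cm <- flat[cbind(pix, idx_of(pmax(by - 1, -sr), bx))]
    cp <- flat[cbind(pix, idx_of(pmin(by + 1, sr), bx))]
    den <- cm - 2 * c0 + cp
    off <- ifelse(ok & den > 0, pmin(pmax((cm - cp) / (2 * den), -0.5), 0.5), 0)
    u_y <- u_y + matrix(off, nr, nc)
    ok <- ok0 & abs(bx) < sr
    cm <- flat[cbind(pix, idx_of(by, pmax(bx - 1, -sr)))]
    cp <- flat[cbind(pix, idx_of(by, pmin(bx + 1, sr)))]
    den <- cm - 2 * c0 + cp
    off <- ifelse(ok & den > 0, pmin(pmax((cm - cp) / (2 * den), -0.5), 0.5), 0)
    u_x <- u_x + matrix(off, nr, nc)
  }

  list(u_y = u_y, u_x = u_x, T = Tm, D = Dm, residual = resid,
       best_int = cbind(shifts$dy[best], shifts$dx[best]))
}

# Lanczos-3 weights for fractional positions f (vector/matrix, clamped to
# (0, 1)): taps at -2..3
.lanczos3_w <- function(f) {
  f <- pmin(pmax(f, 1e-9), 1 - 1e-9)
  out <- vector("list", 6)
  tot <- 0
  for (i in 1:6) {
    x <- (i - 3) - f
    w <- 3 * sin(pi * x) * sin(pi * x / 3) / (pi^2 * x^2)
    out[[i]] <- w
    tot <- tot + w
  }
  lapply(out, function(w) w / tot)
}

# Precompute the gather indices and weights for warping by a displacement
# field (shared across all frames of a stack): out(r) = img(r - u(r)),
# two-pass separable Lanczos-3, replicated edges (content moves by +u).
# A wide windowed-sinc kernel is used because short kernels (bilinear,
# Catmull-Rom) deliver less than the nominal shift at high spatial
# frequencies, which biases iterative displacement refinement on fine
# patterns.
.warp_plan <- function(u_y, u_x) {
  nr <- nrow(u_y); nc <- ncol(u_y)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - u_x
  x0 <- floor(x)
  wx <- .lanczos3_w(x - x0)
  rows <- as.vector(.row(c(nr, nc)))
  xv <- as.vector(x0)
  xi <- lapply(1:6, function(j)
    rows + (pmin(pmax(xv + j - 3L, 1L), nc) - 1L) * nr)
  y <- matrix(seq_len(nr), nr, nc) - u_y
  y0 <- floor(y)
  wy <- .lanczos3_w(y - y0)
  cols <- as.vector(.col(c(nr, nc)))
  yv <- as.vector(y0)
  yi <- lapply(1:6, function(i)
    pmin(pmax(yv + i - 3L, 1L), nr) + (cols - 1L) * nr)
  list(nr = nr, nc = nc, xi = xi, wx = wx, yi = yi, wy = wy)
}

.warp_apply <- function(img, plan) {
  tmp <- plan$wx[[1]] * img[plan$xi[[1]]]
  for (j in 2:6) tmp <- tmp + plan$wx[[j]] * img[plan$xi[[j]]]
  dim(tmp) <- c(plan$nr, plan$nc)
  out <- plan$wy[[1]] * tmp[plan$yi[[1]]]
  for (i in 2:6) out <- out + plan$wy[[i]] * tmp[plan$yi[[i]]]
  matrix(out, plan$nr, plan$nc)
}

.warp_by_field <- function(img, u_y, u_x) {
  .warp_apply(img, .warp_plan(u_y, u_x))
}

#' Windowed pattern matching of sample against reference stacks
#'
#' For every pixel, minimises over candidate integer displacements the
#' windowed, step-summed squared residual of the transmission/dark-field
#' model (see the package vignette), with closed-form least-squares T and D
#' per candidate. Sub-pixel refinement follows the configured scheme; the
#' default iteratively warps the reference stack by the current displacement
#' field and re-matches the residual, which removes most of the
#' pixel-locking bias of one-shot parabola interpolation.
#'
#' @param sample_stack,reference_stack `[step, rows, cols]` arrays or lists
#'   of matrices, equal step counts and shapes, preprocessed.
#' @param config a [match_config()].
#' @return object of class `multimodal_projection`: list with matrices `T`
#'   (transmission), `u_x`, `u_y` (displacement in px, x = columns,
#'   y = rows), `D` (dark-field), `residual` (cost at the optimum),
#'   `n_degenerate` (count of windows with no reference modulation, where D
#'   was fixed to 1).
#' @export
umpa_match <- function(sample_stack, reference_stack, config = match_config()) {
  S <- .as_stack(sample_stack); R <- .as_stack(reference_stack)
  check_that(length(S) == length(R), "sample and reference step counts differ")
  nr <- nrow(S[[1]]); nc <- ncol(S[[1]])
  check_that(all(vapply(c(S, R), function(m) all(dim(m) == c(nr, nc)),
                        logical(1))), "frame shapes differ")
  h <- config$window_half_px; sr <- config$search_radius_px
  darkfield <- config$estimate_darkfield

  st <- .match_stage(S, R, h, sr, darkfield,
                     parabola = config$subpixel != "refine_off")
  u_y <- st$u_y; u_x <- st$u_x

  if (config$subpixel == "iterative") {
    # refinement stays anchored to the stage-1 discrete minimum: it resolves
    # the sub-pixel part only, and cannot wander off to a different cost
    # valley (important for periodic patterns and small step counts)
    m_y <- matrix(st$best_int[, 1], nr, nc)
    m_x <- matrix(st$best_int[, 2], nr, nc)
    # iterate on mildly band-limited copies: the interpolating warp is
    # phase-accurate below ~0.3 cycles/px, so matching is restricted to
    # that band (displacement information is preserved there)
    Sb <- lapply(S, gauss_blur, sigma = 0.5)
    Rb <- lapply(R, gauss_blur, sigma = 0.5)
    for (it in seq_len(config$n_iter)) {
      plan <- .warp_plan(u_y, u_x)
      Rw <- lapply(Rb, .warp_apply, plan = plan)
      stw <- .match_stage(Sb, Rw, h, 1L, darkfield, parabola = TRUE)
      u_y <- pmin(pmax(u_y + stw$u_y, m_y - 1), m_y + 1)
      u_x <- pmin(pmax(u_x + stw$u_x, m_x - 1), m_x + 1)
    }
    # T, D and the residual are re-estimated on the unfiltered data at the
    # converged displacement
    plan <- .warp_plan(u_y, u_x)
    Rw <- lapply(R, .warp_apply, plan = plan)
    stf <- .match_stage(S, Rw, h, 1L, darkfield, parabola = FALSE)
    st$T <- stf$T; st$D <- stf$D; st$residual <- stf$residual
  }

  M <- length(S)
  n_degen <- 0
  if (darkfield) {
    Rbar <- Reduce(`+`, R) / M
    R2 <- Reduce(`+`, lapply(R, function(m) m * m))
    Atil2 <- win_sum(R2 - M * Rbar * Rbar, h)
    n_degen <- sum(Atil2 <= .Machine$double.eps)
  }

  structure(list(T = st$T, u_x = u_x, u_y = u_y, D = st$D,
                 residual = st$residual, n_degenerate = n_degen,
                 config = config),
            class = "multimodal_projection")
}

#' @export
print.multimodal_projection <- function(x, ...) {
  cat(sprintf(paste0("<multimodal_projection> %d x %d px; T in [%.3g, %.3g], ",
                     "|u| <= %.2f px, D mean %.3g\n"),
              nrow(x$T), ncol(x$T), min(x$T), max(x$T),
              max(abs(c(x$u_x, x$u_y))), mean(x$D)))
  invisible(x)
}

#' Convert pattern displacements to refraction angles
#'
#' Small-angle conversion `alpha_i = u_i * pixel / z_eff`, with `z_eff` the
#' effective propagation distance over which a refracted ray accumulates its
#' transverse displacement (default: the sample-to-detector distance).
#'
#' @param u_maps a [umpa_match()] result, or a list with `u_x`, `u_y` in px.
#' @param detector a [detector_model()] (provides the pixel pitch).
#' @param geometry a [scan_geometry()].
#' @param z_eff_m effective distance (m); defaults to `geometry$z_prop_m`.
#' @return object of class `refraction_angle_map`: list with `alpha_x`,
#'   `alpha_y` in rad.
#' @export
displacements_to_angles <- function(u_maps, detector, geometry,
                                    z_eff_m = NULL) {
  z <- z_eff_m %||% geometry$z_prop_m
  check_that(z > 0, "z_eff must be > 0")
  p_m <- detector$pixel_um * 1e-6
  structure(list(alpha_x = u_maps$u_x * p_m / z,
                 alpha_y = u_maps$u_y * p_m / z),
            class = "refraction_angle_map")
}

#' Convert refraction angles to differential phase
#'
#' `dPhi/dx = k * alpha_x`, `dPhi/dy = k * alpha_y` (rad per metre of
#' sample-plane coordinate).
#'
#' @param alpha_maps a [displacements_to_angles()] result.
#' @param beam a [beam_config()].
#' @param pixel_um sampling pitch carried on to the gradient field.
#' @return a [gradient_field()].
#' @export
angles_to_dpc <- function(alpha_maps, beam, pixel_um = 1.28) {
  gradient_field(gx = beam$wavenumber * alpha_maps$alpha_x,
                 gy = beam$wavenumber * alpha_maps$alpha_y,
                 pixel_um = pixel_um)
}
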