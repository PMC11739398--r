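# Soft-tissue phantom emulating a paraffin-embedded placenta specimen:
# a paraffin cylinder containing branching tubular villi of soft tissue with
# vessel lumina and sparse ~6 micron "blood cell" spheres.

#' Phantom container
#'
#' @param label_volume 3D integer array `[z, y, x]` of material labels
#'   (z = vertical / rotation axis).
#' @param materials named list mapping label (as character) to a material
#'   name or custom optical constants.
#' @param voxel_um isotropic voxel size (microns).
#' @param energy_keV energy at which the ground-truth delta/beta maps are
#'   tabulated.
#' @return object of class `phantom` with `ground_truth_delta` and
#'   `ground_truth_beta` arrays populated.
#' @export
phantom <- function(label_volume, materials, voxel_um, energy_keV = 20) {
  labs <- sort(unique(as.integer(label_volume)))
  check_that(all(as.character(labs) %in% names(materials)),
             "all labels in label_volume must be present in materials")
  oc <- lapply(materials, optical_constants, energy_keV = energy_keV)
  dl <- vapply(oc, `[[`, numeric(1), "delta")
  bl <- vapply(oc, `[[`, numeric(1), "beta")
  gt_d <- array(dl[as.character(label_volume)], dim = dim(label_volume))
  gt_b <- array(bl[as.character(label_volume)], dim = dim(label_volume))
  structure(list(label_volume = label_volume, materials = materials,
                 optical = oc, voxel_um = voxel_um, energy_keV = energy_keV,
                 ground_truth_delta = gt_d, ground_truth_beta = gt_b),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$label_volume)
  cat(sprintf("<phantom> %d x %d x %d voxels @ %.3g um, materials: %s\n",
              d[1], d[2], d[3], x$voxel_um,
              paste(vapply(x$optical, `[[`, character(1), "material_name"),
                    collapse = ", ")))
  invisible(x)
}

# draw a solid sphere into a label array (by reference semantics via return)
.draw_sphere <- function(lab, centre, r_vox, value) {
  d <- dim(lab)
  lo <- pmax(1L, floor(centre - r_vox)); hi <- pmin(d, ceiling(centre + r_vox))
  if (any(lo > hi)) return(lab)
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  dz2 <- (zz - centre[1])^2; dy2 <- (yy - centre[2])^2; dx2 <- (xx - centre[3])^2
  m <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r_vox^2
  sub <- lab[zz, yy, xx, drop = FALSE]
  sub[m] <- value
  lab[zz, yy, xx] <- sub
  lab
}

#' Synthetic placenta-like phantom
#'
#' Builds a paraffin cylinder containing a main stem villus running along the
#' rotation axis, randomly branching tubular villi of soft tissue, internal
#' vessel lumina, and sparse ~6 micron blood-cell spheres. The stem villus
#' guarantees that every axial slice contains both tissue and paraffin, which
#' the quantitative tests rely on.
#'
#' Labels: 0 air, 1 paraffin, 2 soft tissue, 3 vessel lumen (water),
#' 4 blood cell.
#'
#' @param shape_vox `c(nz, ny, nx)` (<= 512 per axis).
#' @param voxel_um isotropic voxel size (microns).
#' @param seed RNG seed; the phantom is deterministic given the seed.
#' @param energy_keV beam energy for the ground-truth optical constants.
#' @param n_branches number of random villous branches.
#' @param n_cells number of blood cells.
#' @param villus_radius_um radius of the stem villus (microns).
#' @return a [phantom()].
#' @export
make_placenta_phantom <- function(shape_vox = c(128, 128, 128), voxel_um = 1.1,
                                  seed = 1, energy_keV = 20, n_branches = 8,
                                  n_cells = 30, villus_radius_um = 14) {
  check_that(all(shape_vox <= 512), "phantom limited to 512^3 voxels")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  nz <- shape_vox[1]; ny <- shape_vox[2]; nx <- shape_vox[3]
  lab <- array(0L, dim = shape_vox)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  r_cyl <- 0.42 * min(ny, nx)
  d2 <- outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, `+`)
  cyl <- d2 <= r_cyl^2
  for (z in seq_len(nz)) lab[z, , ][cyl] <- 1L

  r_villus <- villus_radius_um / voxel_um
  # main stem villus: straight tube along z, off-centre so the axial slice
  # has distinct tissue and paraffin regions
  stem_y <- cy + 0.16 * ny; stem_x <- cx
  for (z in seq_len(nz))
    lab <- .draw_sphere(lab, c(z, stem_y, stem_x), r_villus, 2L)
  # its vessel lumen
  for (z in seq_len(nz))
    lab <- .draw_sphere(lab, c(z, stem_y, stem_x), 0.4 * r_villus, 3L)

  # random branching villi: short random walks starting near the stem
  for (b in seq_len(n_branches)) {
    pos <- c(runif(1, 0.2, 0.8) * nz, stem_y, stem_x)
    dir <- c(runif(1, -0.5, 0.5), runif(1, -1, 1), runif(1, -1, 1))
    dir <- dir / sqrt(sum(dir^2))
    r_b <- r_villus * runif(1, 0.45, 0.8)
    n_step <- round(runif(1, 20, 45))
    for (s in seq_len(n_step)) {
      pos <- pos + dir * 1.5
      dir <- dir + c(rnorm(1, 0, 0.12), rnorm(1, 0, 0.12), rnorm(1, 0, 0.12))
      dir <- dir / sqrt(sum(dir^2))
      inside <- (pos[2] - cy)^2 + (pos[3] - cx)^2 < (r_cyl - r_b - 1)^2 &&
        pos[1] > 1 + r_b && pos[1] < nz - r_b
      if (!inside) break
      lab <- .draw_sphere(lab, pos, r_b, 2L)
      if (r_b > 3) lab <- .draw_sphere(lab, pos, 0.35 * r_b, 3L)
    }
  }

  # sparse blood cells (~6 um spheres) inside the cylinder
  r_cell <- 3 / voxel_um  # 6 um diameter
  placed <- 0; tries <- 0
  while (placed < n_cells && tries < n_cells * 50) {
    tries <- tries + 1
    p <- c(runif(1, 1 + r_cell, nz - r_cell),
           cy + runif(1, -1, 1) * (r_cyl - r_cell - 2),
           cx + runif(1, -1, 1) * (r_cyl - r_cell - 2))
    if ((p[2] - cy)^2 + (p[3] - cx)^2 >= (r_cyl - r_cell - 1)^2) next
    lab <- .draw_sphere(lab, p, r_cell, 4L)
    placed <- placed + 1
  }

  phantom(lab,
          materials = list(`0` = "air", `1` = "paraffin", `2` = "soft_tissue",
                           `3` = "water", `4` = "blood"),
          voxel_um = voxel_um, energy_keV = energy_keV)
}

#' Project a phantom along the beam
#'
#' Line integrals of delta and beta through the phantom at the given rotation
#' about the vertical (z) axis, sampled on the detector grid (one detector
#' row per phantom z-slice). Angle 0 integrates along the +x axis; rotation
#' follows the tomographic convention used by [fbp_reconstruct()].
#'
#' @param phantom a [phantom()].
#' @param angle_deg rotation angle in `[0, 180)` degrees (values outside are
#'   accepted and wrapped by periodicity of the geometry).
#' @return list with `delta_t_map` and `beta_t_map` (matrices `[z, u]`,
#'   units: m).
#' @export
project_phantom <- function(phantom, angle_deg) {
  vol_d <- phantom$ground_truth_delta
  vol_b <- phantom$ground_truth_beta
  d <- dim(vol_d); nz <- d[1]; ny <- d[2]; nx <- d[3]
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  n_u <- nx
  u <- seq_len(n_u) - cx
  svals <- seq_len(nx) - cx
  Vd <- matrix(vol_d, nz, ny * nx)
  Vb <- matrix(vol_b, nz, ny * nx)
  Pd <- matrix(0, nz, n_u)
  Pb <- matrix(0, nz, n_u)
  for (s in svals) {
    # ray point: (x, y) = centre + u * perp + s * dir, dir = (cos, sin)
    x <- cx + u * (-st) + s * ct
    y <- cy + u * ct + s * st
    ok <- x >= 1 & x <= nx - 1e-9 & y >= 1 & y <= ny - 1e-9
    if (!any(ok)) next
    xo <- x[ok]; yo <- y[ok]
    x0 <- pmin(floor(xo), nx - 1); y0 <- pmin(floor(yo), ny - 1)
    wx <- xo - x0; wy <- yo - y0
    i00 <- y0 + (x0 - 1) * ny
    i10 <- i00 + 1
    i01 <- i00 + ny
    i11 <- i01 + 1
    w00 <- (1 - wy) * (1 - wx); w10 <- wy * (1 - wx)
    w01 <- (1 - wy) * wx;       w11 <- wy * wx
    idx <- which(ok)
    Pd[, idx] <- Pd[, idx] +
      Vd[, i00, drop = FALSE] * rep(w00, each = nz) +
      Vd[, i10, drop = FALSE] * rep(w10, each = nz) +
      Vd[, i01, drop = FALSE] * rep(w01, each = nz) +
      Vd[, i11, drop = FALSE] * rep(w11, each = nz)
    Pb[, idx] <- Pb[, idx] +
      Vb[, i00, drop = FALSE] * rep(w00, each = nz) +
      Vb[, i10, drop = FALSE] * rep(w10, each = nz) +
      Vb[, i01, drop = FALSE] * rep(w01, each = nz) +
      Vb[, i11, drop = FALSE] * rep(w11, each = nz)
  }
  vox_m <- phantom$voxel_um * 1e-6
  list(delta_t_map = Pd * vox_m, beta_t_map = Pb * vox_m)
}
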