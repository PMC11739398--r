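# Wavefront marker (modulator) screens: hexagonal Talbot array illuminator
# (TAI) phase gratings and stacked-sandpaper diffusers, plus the transverse
# stepping patterns used to scan them.

#' Modulator screen container
#'
#' @param kind `"tai_hex"` or `"sandpaper"`.
#' @param thickness_map_um 2D projected-thickness map (microns, >= 0).
#' @param material material name or custom optical constants (see
#'   [optical_constants()]).
#' @param pixel_um sampling pitch of the thickness map (microns).
#' @param params list of generation parameters (kept for provenance).
#' @return object of class `modulator_screen`.
#' @export
modulator_screen <- function(kind, thickness_map_um, material, pixel_um,
                             params = list()) {
  check_that(all(thickness_map_um >= 0), "thickness map must be >= 0")
  structure(list(kind = kind, thickness_map_um = thickness_map_um,
                 material = material, pixel_um = pixel_um, params = params),
            class = "modulator_screen")
}

#' @export
print.modulator_screen <- function(x, ...) {
  cat(sprintf("<modulator_screen> %s, %d x %d px @ %.3g um/px\n",
              x$kind, nrow(x$thickness_map_um), ncol(x$thickness_map_um),
              x$pixel_um))
  invisible(x)
}

#' Hexagonal Talbot array illuminator screen
#'
#' Binary phase grating: a hexagonal lattice of etched cells whose area
#' fraction equals the duty cycle. The defaults reproduce a 7 micron period
#' silicon TAI with duty cycle 1/3 and 17 micron etch depth, whose
#' peak-to-trough phase shift at 20 keV is close to 2*pi/3.
#'
#' @param period_um lattice period (microns); must exceed `2 * pixel_um`.
#' @param duty_cycle etched-area fraction, in (0, 1).
#' @param etch_depth_um etch depth (microns).
#' @param material etched wafer material (default `"silicon"`).
#' @param pixel_um sampling pitch (microns).
#' @param shape_px map size `c(rows, cols)`.
#' @return [modulator_screen()] of kind `"tai_hex"` with a thickness map in
#'   `{0, etch_depth_um}` (etched cells have thickness 0; the surrounding
#'   wafer web retains the etch depth, so the etched fraction is the fraction
#'   of zero-thickness pixels).
#' @export
make_tai_screen <- function(period_um = 7, duty_cycle = 1 / 3,
                            etch_depth_um = 17, material = "silicon",
                            pixel_um = 1.28, shape_px = c(256, 256)) {
  check_that(duty_cycle > 0 && duty_cycle < 1, "duty_cycle must be in (0,1)")
  if (period_um <= 2 * pixel_um)
    stop(sprintf(paste0("TAI period %.3g um is under-sampled at %.3g um/px; ",
                        "need period > 2*pixel_um (>= 4 px/period recommended)"),
                 period_um, pixel_um))
  nr <- shape_px[1]; nc <- shape_px[2]
  p <- period_um / pixel_um                    # period in px
  # hex lattice vectors a1 = (p, 0), a2 = (p/2, p*sqrt(3)/2) in (x, y) px
  # cell area = p^2*sqrt(3)/2; etched discs of radius r give the duty cycle
  r <- p * sqrt(duty_cycle * sqrt(3) / (2 * pi))
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1, nr, nc)
  # fractional lattice coordinates
  u <- x / p - y / (p * sqrt(3))
  v <- 2 * y / (p * sqrt(3))
  d2min <- matrix(Inf, nr, nc)
  for (du in -1:1) for (dv in -1:1) {
    uu <- round(u) + du; vv <- round(v) + dv
    sx <- uu * p + vv * p / 2
    sy <- vv * p * sqrt(3) / 2
    d2min <- pmin(d2min, (x - sx)^2 + (y - sy)^2)
  }
  thick <- matrix(etch_depth_um, nr, nc)
  thick[d2min <= r^2] <- 0
  modulator_screen("tai_hex", thick, material, pixel_um,
                   params = list(period_um = period_um, duty_cycle = duty_cycle,
                                 etch_depth_um = etch_depth_um))
}

#' Stacked-sandpaper diffuser screen
#'
#' Sums `n_layers` of randomly placed spherical-cap grains whose lateral
#' diameter is log-normal with the stated mean (the grit specification gives
#' only a mean grain size). Deterministic under a fixed seed.
#'
#' @param grain_mean_um mean lateral grain size (microns).
#' @param n_layers number of sandpaper sheets stacked (0 gives a uniform
#'   zero-thickness screen); layer-to-layer spacing is treated as negligible
#'   and all layers are summed into one projected-thickness map.
#' @param material grain material (default `"silicon_carbide"`).
#' @param pixel_um sampling pitch (microns).
#' @param shape_px map size `c(rows, cols)`.
#' @param seed RNG seed.
#' @param sdlog log-normal shape parameter of the lateral diameter.
#' @param coverage mean grain footprints per unit area, per layer.
#' @return [modulator_screen()] of kind `"sandpaper"`.
#' @export
make_sandpaper_screen <- function(grain_mean_um = 5.8, n_layers = 6,
                                  material = "silicon_carbide",
                                  pixel_um = 1.28, shape_px = c(256, 256),
                                  seed = 1, sdlog = 0.35, coverage = 1.0) {
  check_that(grain_mean_um > 0, "grain_mean_um must be > 0")
  check_that(n_layers >= 0, "n_layers must be >= 0")
  nr <- shape_px[1]; nc <- shape_px[2]
  thick <- matrix(0, nr, nc)
  if (n_layers >= 1) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    meanlog <- log(grain_mean_um) - sdlog^2 / 2
    area_px <- nr * nc
    grain_area_px <- pi * (grain_mean_um / (2 * pixel_um))^2
    n_grains <- ceiling(coverage * area_px / grain_area_px)
    for (layer in seq_len(n_layers)) {
      cy <- runif(n_grains, 0.5, nr + 0.5)
      cx <- runif(n_grains, 0.5, nc + 0.5)
      R_px <- stats::rlnorm(n_grains, meanlog, sdlog) / (2 * pixel_um)
      for (g in seq_len(n_grains)) {
        r <- R_px[g]
        y1 <- max(1L, floor(cy[g] - r)); y2 <- min(nr, ceiling(cy[g] + r))
        x1 <- max(1L, floor(cx[g] - r)); x2 <- min(nc, ceiling(cx[g] + r))
        if (y1 > y2 || x1 > x2) next
        yy <- (y1:y2) - cy[g]; xx <- (x1:x2) - cx[g]
        d2 <- outer(yy^2, xx^2, `+`)
        cap <- r^2 - d2
        cap[cap < 0] <- 0
        thick[y1:y2, x1:x2] <- thick[y1:y2, x1:x2] +
          2 * sqrt(cap) * pixel_um   # chord through a sphere, in microns
      }
    }
  }
  modulator_screen("sandpaper", thick, material, pixel_um,
                   params = list(grain_mean_um = grain_mean_um,
                                 n_layers = n_layers, seed = seed,
                                 sdlog = sdlog, coverage = coverage))
}

#' Peak-to-trough phase shift of a screen
#'
#' For a binary TAI this is `k * delta(E) * etch_depth`; for a general screen
#' the difference between the 99.5th and 0.5th thickness percentiles is used.
#'
#' @param screen a [modulator_screen()].
#' @param beam a [beam_config()].
#' @return phase shift in radians.
#' @examples
#' s <- make_tai_screen(7, 1/3, 17, "silicon", 1.28, c(64, 64))
#' screen_phase_shift(s, beam_config(20))  # ~2*pi/3
#' @export
screen_phase_shift <- function(screen, beam) {
  oc <- optical_constants(screen$material, beam$energy_keV)
  t_range <- if (screen$kind == "tai_hex") {
    screen$params$etch_depth_um
  } else {
    diff(stats::quantile(screen$thickness_map_um, c(0.005, 0.995), names = FALSE))
  }
  beam$wavenumber * oc$delta * t_range * 1e-6
}

#' Modulator stepping pattern
#'
#' Ordered transverse modulator offsets. The `"tilted_grid"` scheme tiles one
#' TAI unit cell with a sheared 4x4-style grid (16 steps scan the cell with
#' all offsets distinct modulo the lattice); the `"spiral"` scheme places
#' steps on a Fermat spiral, suited to random diffusers.
#'
#' @param scheme `"tilted_grid"` or `"spiral"`.
#' @param n_steps number of steps (default 16 for the tilted grid, 20 for the
#'   spiral).
#' @param period_um TAI lattice period (tilted grid only).
#' @param pixel_um detector pixel pitch, used to express offsets in px.
#' @param spiral_scale_px radial scale of the Fermat spiral (px).
#' @return object of class `stepping_pattern` with `offsets_px` (n x 2 matrix
#'   of (dy, dx) offsets in px) and `scheme`.
#' @export
stepping_pattern <- function(scheme = c("tilted_grid", "spiral"),
                             n_steps = NULL, period_um = 7, pixel_um = 1.28,
                             spiral_scale_px = 2.5) {
  scheme <- match.arg(scheme)
  if (scheme == "tilted_grid") {
    n_steps <- n_steps %||% 16L
    m <- round(sqrt(n_steps))
    check_that(m * m == n_steps, "tilted_grid needs a square number of steps")
    p <- period_um / pixel_um
    i <- (seq_len(n_steps) - 1) %% m
    j <- (seq_len(n_steps) - 1) %/% m
    # sheared grid: u advances by 1/n_steps per row so the m x m grid tiles
    # the unit cell with n distinct positions along each lattice axis
    u <- i / m + j / n_steps
    v <- j / m
    dx <- u * p + v * p / 2
    dy <- v * p * sqrt(3) / 2
    offs <- cbind(dy, dx)
  } else {
    n_steps <- n_steps %||% 20L
    i <- seq_len(n_steps) - 1
    golden <- pi * (3 - sqrt(5))
    r <- spiral_scale_px * sqrt(i)
    offs <- cbind(r * sin(i * golden), r * cos(i * golden))
  }
  dimnames(offs) <- list(NULL, c("dy", "dx"))
  structure(list(offsets_px = offs, scheme = scheme), class = "stepping_pattern")
}
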