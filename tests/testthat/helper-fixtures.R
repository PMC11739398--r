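# Shared simulated fixtures, built once per test run (all generated in code;
# nothing on disk).

.fixtures <- new.env(parent = emptyenv())

# 16-step TAI reference stack on a 64^2 detector, noise-free, with the
# screen fields kept for building matched sample frames.
tai_fixture <- function() {
  if (!is.null(.fixtures$tai64)) return(.fixtures$tai64)
  b <- beam_config(20)
  geo <- scan_geometry()
  det <- detector_model(shape_px = c(64, 64), photons_per_px = 1e4)
  scr <- make_tai_screen(shape_px = c(96, 96))
  steps <- stepping_pattern("tilted_grid", 16)
  fields <- lapply(1:16, function(s)
    fresnel_propagate(xpci:::screen_field(scr, det$shape_px,
                                          steps$offsets_px[s, ], b),
                      geo$z0_m, b, det$pixel_um))
  refs <- lapply(1:16, function(s)
    simulate_frame(geo, b, det, screen = scr, noise = FALSE,
                   sample_plane_field = fields[[s]]))
  .fixtures$tai64 <- list(beam = b, geo = geo, det = det, screen = scr,
                          stepping = steps, fields = fields, refs = refs)
  .fixtures$tai64
}

# sample frames for the TAI fixture with a given thin-object delta_t map (m)
tai_sample_frames <- function(fx, delta_t_map, beta_t_map = NULL) {
  beta_t_map <- beta_t_map %||% delta_t_map * 0
  lapply(fx$fields, function(f) {
    U <- f * xpci:::object_transmission(delta_t_map, beta_t_map, fx$beam)
    I <- Mod(fresnel_propagate(U, fx$geo$z_prop_m, fx$beam,
                               fx$det$pixel_um))^2
    xpci:::gauss_blur(I, fx$det$psf_fwhm_px / (2 * sqrt(2 * log(2)))) *
      fx$det$photons_per_px
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

poisson_frames <- function(frames, seed) {
  withr::with_seed(seed, lapply(frames, function(f)
    matrix(stats::rpois(length(f), pmax(f, 0)), nrow(f))))
}
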