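# On-disk scan layout: a directory of 32-bit float TIFF stacks plus a YAML
# metadata sidecar.
#
#   <dir>/meta.yaml
#   <dir>/dark.tif                  (one page per dark frame)
#   <dir>/reference/step_<i>.tif    (one page per repeat)
#   <dir>/sample/step_<i>.tif       (one page per angle)

.write_stack_tiff <- function(frames3d, path, scale) {
  pages <- lapply(seq_len(dim(frames3d)[1]), function(i) frames3d[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
}

.read_stack_tiff <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]] * scale
  out
}

#' Write a simulated scan to a directory of TIFF stacks
#'
#' @param scan a [simulate_scan()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_dir <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "reference"), showWarnings = FALSE)
  dir.create(file.path(dir, "sample"), showWarnings = FALSE)
  # 32-bit float TIFF stores [0,1]; scale by a power of two above the max
  scale <- 2^ceiling(log2(max(scan$sample, scan$reference, scan$dark, 1)))
  cfg <- scan$config
  n_step <- dim(scan$sample)[1]
  .write_stack_tiff(scan$dark, file.path(dir, "dark.tif"), scale)
  for (s in seq_len(n_step)) {
    .write_stack_tiff(scan$reference[s, , , , drop = TRUE] |>
                        array(dim(scan$reference)[-1]),
                      file.path(dir, "reference", sprintf("step_%02d.tif", s)),
                      scale)
    .write_stack_tiff(scan$sample[s, , , , drop = TRUE] |>
                        array(dim(scan$sample)[-1]),
                      file.path(dir, "sample", sprintf("step_%02d.tif", s)),
                      scale)
  }
  meta <- list(
    energy_keV = cfg$beam$energy_keV,
    pixel_um = cfg$detector$pixel_um,
    z_prop_m = cfg$geometry$z_prop_m,
    z0_m = cfg$geometry$z0_m,
    n_step = n_step,
    n_angles = length(scan$angles_deg),
    angles_deg = as.numeric(scan$angles_deg),
    intensity_scale = scale,
    stepping_offsets_px = if (!is.null(cfg$stepping))
      lapply(seq_len(nrow(cfg$stepping$offsets_px)),
             function(i) as.numeric(cfg$stepping$offsets_px[i, ]))
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a scan directory written by [write_scan_dir()]
#'
#' @param dir scan directory.
#' @return list with `dark`, `reference`, `sample` arrays, `angles_deg` and
#'   the `meta` list.
#' @export
read_scan_dir <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  scale <- meta$intensity_scale
  dark <- .read_stack_tiff(file.path(dir, "dark.tif"), scale)
  n_step <- meta$n_step
  ref1 <- .read_stack_tiff(file.path(dir, "reference", "step_01.tif"), scale)
  sam1 <- .read_stack_tiff(file.path(dir, "sample", "step_01.tif"), scale)
  reference <- array(0, c(n_step, dim(ref1)))
  sample <- array(0, c(n_step, dim(sam1)))
  reference[1, , , ] <- ref1; sample[1, , , ] <- sam1
  for (s in seq_len(n_step)[-1]) {
    reference[s, , , ] <- .read_stack_tiff(
      file.path(dir, "reference", sprintf("step_%02d.tif", s)), scale)
    sample[s, , , ] <- .read_stack_tiff(
      file.path(dir, "sample", sprintf("step_%02d.tif", s)), scale)
  }
  list(dark = dark, reference = reference, sample = sample,
       angles_deg = as.numeric(meta$angles_deg), meta = meta)
}
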