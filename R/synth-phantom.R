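# Synthetic 4D phantom with a logistic liver-lung intensity edge. The phantom
# stands in for the coronal liver-lung region where the navigator beam sits:
# bright liver below, dark lung above, separated along z by a sigmoid edge of
# known width, with optional per-frame motion blur and Gaussian noise.

#' Specification of a synthetic liver-lung phantom
#'
#' @param shape Integer vector `(nx, ny, nz, nt)` of voxels / time frames.
#' @param liver_intensity Mean liver signal (a.u.); must exceed `lung_intensity`.
#' @param lung_intensity Mean lung signal (a.u.), >= 0.
#' @param edge_z0 Edge centre along z, in voxel units; inside `(0, nz)`.
#' @param edge_width_w Logistic scale parameter of the edge, voxels, > 0.
#' @param noise_sd Gaussian noise SD per voxel (a.u.).
#' @param motion_blur_sd SD of per-frame z-shifts (voxels) averaged into each
#'   frame to mimic respiratory blurring of an ungated reconstruction; 0 = no
#'   blur.
#' @param seed RNG seed.
#' @return A list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(edge_width_w = 2, noise_sd = 5)
#' @export
phantom_spec <- function(shape = c(10L, 10L, 30L, 5L),
                         liver_intensity = 100, lung_intensity = 0,
                         edge_z0 = NULL, edge_width_w = 2,
                         noise_sd = 0, motion_blur_sd = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 4L || any(shape < 1L)) {
    abort("`shape` must be four positive integers (nx, ny, nz, nt).")
  }
  edge_z0 <- edge_z0 %||% (shape[3] / 2)
  if (!(liver_intensity > lung_intensity && lung_intensity >= 0)) {
    abort("need `liver_intensity` > `lung_intensity` >= 0.")
  }
  if (!(edge_z0 > 0 && edge_z0 < shape[3])) abort("`edge_z0` must lie inside (0, nz).")
  if (edge_width_w <= 0) abort("`edge_width_w` must be > 0.")
  if (noise_sd < 0 || motion_blur_sd < 0) abort("SDs must be >= 0.")
  structure(
    list(
      shape = shape, liver_intensity = liver_intensity,
      lung_intensity = lung_intensity, edge_z0 = edge_z0,
      edge_width_w = edge_width_w, noise_sd = noise_sd,
      motion_blur_sd = motion_blur_sd, seed = seed
    ),
    class = "phantom_spec"
  )
}

#' Generate a 4D phantom volume
#'
#' Intensity along z follows
#' `lung + (liver - lung) * plogis((z - z0) / w)` (dark lung at low z rising
#' to bright liver at high z) plus i.i.d. Gaussian noise per voxel and frame. With
#' `motion_blur_sd > 0` each frame is the average of 16 copies of the clean
#' profile shifted along z by Gaussian offsets, which widens the effective
#' edge the way respiratory motion blurs an ungated reconstruction. The
#' ground-truth width is kept in the `spec` element.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_volume` with elements `data` (4D array)
#'   and `spec`.
#' @examples
#' vol <- gen_phantom_volume(phantom_spec(noise_sd = 5, seed = 3))
#' dim(vol$data)
#' @export
gen_phantom_volume <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, as.list(spec))
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]; nt <- spec$shape[4]
  z <- seq_len(nz)
  clean_profile <- function(shift) {
    spec$lung_intensity + (spec$liver_intensity - spec$lung_intensity) *
      stats::plogis((z - (spec$edge_z0 + shift)) / spec$edge_width_w)
  }
  with_seed(spec$seed, {
    vol <- array(0, dim = c(nx, ny, nz, nt))
    for (f in seq_len(nt)) {
      prof <- if (spec$motion_blur_sd > 0) {
        shifts <- rnorm(16L, sd = spec$motion_blur_sd)
        rowMeans(vapply(shifts, clean_profile, numeric(nz)))
      } else {
        clean_profile(0)
      }
      frame <- array(rep(prof, each = nx * ny), dim = c(nx, ny, nz))
      if (spec$noise_sd > 0) {
        frame <- frame + array(rnorm(nx * ny * nz, sd = spec$noise_sd),
                               dim = c(nx, ny, nz))
      }
      vol[, , , f] <- frame
    }
    structure(list(data = vol, spec = spec), class = "phantom_volume")
  })
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<phantom_volume> %d x %d x %d voxels, %d frames; true edge width %g voxel\n",
    d[1], d[2], d[3], d[4], x$spec$edge_width_w
  ))
  invisible(x)
}
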