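# Quantitative image quality from a 4D magnitude volume: region-of-interest
# SNR (time-averaged liver-slice mean over time-averaged lung-slice SD) and
# the liver-lung edge (LLE) sharpness metric -- the mean logistic width of
# sigmoid fits to the through-edge line profiles of a 10 x 10 x 30 voxel ROI.

#' Region-of-interest specification
#'
#' The ROI is a `size` voxel box with `origin` at its lowest corner (1-based
#' voxel indices), oriented so z runs through the liver-lung edge. Two
#' transversal slices inside the ROI are designated: `liver_slice_z` (signal
#' area) and `lung_slice_z` (noise area), both as z-indices *within* the ROI.
#'
#' @param origin Integer `(x, y, z)` of the ROI corner.
#' @param size Integer `(nx, ny, nz)`; default `c(10, 10, 30)`.
#' @param liver_slice_z,lung_slice_z Slice indices within 1..`size[3]`.
#' @return A list of class `roi_spec`.
#' @examples
#' roi_spec(liver_slice_z = 28, lung_slice_z = 3)
#' @export
roi_spec <- function(origin = c(1L, 1L, 1L), size = c(10L, 10L, 30L),
                     liver_slice_z = size[3] - 1L, lung_slice_z = 2L) {
  origin <- as.integer(origin); size <- as.integer(size)
  if (length(origin) != 3L || length(size) != 3L || any(size < 1L)) {
    abort("`origin` and `size` must be length-3 positive integer vectors.")
  }
  if (liver_slice_z == lung_slice_z) abort("liver and lung slices must differ.")
  if (any(c(liver_slice_z, lung_slice_z) < 1L) ||
      any(c(liver_slice_z, lung_slice_z) > size[3])) {
    abort("slice indices must lie inside the ROI z-extent.")
  }
  structure(
    list(origin = origin, size = size,
         liver_slice_z = as.integer(liver_slice_z),
         lung_slice_z = as.integer(lung_slice_z)),
    class = "roi_spec"
  )
}

# 4D sub-array for the ROI, with bounds checking
roi_array <- function(volume, roi) {
  arr <- if (inherits(volume, "phantom_volume")) volume$data else volume
  d <- dim(arr)
  if (length(d) == 3L) { dim(arr) <- c(d, 1L); d <- dim(arr) }
  if (length(d) != 4L) abort("volume must be a 4D (x, y, z, t) array.")
  hi <- roi$origin + roi$size - 1L
  if (any(roi$origin < 1L) || any(hi > d[1:3])) {
    abort("ROI extends outside the volume bounds.")
  }
  arr[roi$origin[1]:hi[1], roi$origin[2]:hi[2], roi$origin[3]:hi[3], , drop = FALSE]
}

#' ROI signal-to-noise ratio
#'
#' SNR = (time-averaged spatial mean of the liver slice) /
#' (time-averaged spatial SD of the lung slice), with the sample SD (n - 1).
#' A noise-free volume (lung SD 0) yields `Inf` as a sentinel rather than an
#' error.
#'
#' @param volume A `phantom_volume` or 4D array (x, y, z, t).
#' @param roi A [roi_spec()].
#' @return SNR (unitless scalar).
#' @export
compute_snr <- function(volume, roi) {
  a <- roi_array(volume, roi)
  nt <- dim(a)[4]
  liver <- vapply(seq_len(nt), function(f) mean(a[, , roi$liver_slice_z, f]), numeric(1))
  lung <- vapply(seq_len(nt), function(f) sd(as.vector(a[, , roi$lung_slice_z, f])), numeric(1))
  num <- mean(liver); den <- mean(lung)
  if (den == 0) return(Inf)
  num / den
}

#' Extract time-averaged through-edge line profiles
#'
#' One z-profile per in-plane (x, y) position of the ROI, averaged over time
#' frames: 100 profiles of length 30 for the default 10 x 10 x 30 ROI (other
#' in-plane sizes give `nx * ny` profiles).
#'
#' @inheritParams compute_snr
#' @return A numeric matrix, `size[3]` rows (z) by `nx * ny` columns.
#' @export
extract_profiles <- function(volume, roi) {
  a <- roi_array(volume, roi)
  d <- dim(a)
  if (d[3] < 2L) abort("ROI z-extent is degenerate; need >= 2 slices.")
  ta <- apply(a, c(1, 2, 3), mean) # time average
  matrix(aperm(ta, c(3, 1, 2)), nrow = d[3], ncol = d[1] * d[2])
}

#' Fit a logistic sigmoid to one line profile
#'
#' Model: `f(z) = b + a / (1 + exp(-(z - z0) / w))`, fitted by bounded
#' Levenberg-Marquardt least squares. Initial values are `b = min(profile)`,
#' `a = range`, `z0` at the steepest gradient, `w = 2` voxels; `w` is bounded
#' to `(0.05, nz]` and `a` to positive. `converged` is `FALSE` (never an
#' error) when the optimizer fails or a bound is hit degenerately.
#'
#' @param profile Numeric vector of >= 5 intensities along z.
#' @return A one-row tibble `b`, `a`, `z0`, `w`, `converged`.
#' @export
fit_sigmoid_profile <- function(profile) {
  nz <- length(profile)
  if (nz < 5L) abort("profile needs at least 5 points.")
  if (diff(range(profile)) == 0) {
    return(tibble(b = profile[1], a = 0, z0 = NA_real_, w = NA_real_,
                  converged = FALSE))
  }
  z <- seq_len(nz)
  # initial edge centre: mid-level crossing of a lightly smoothed profile,
  # which is far more robust to voxel noise than the raw steepest gradient
  sm <- stats::filter(profile, rep(1 / 3, 3))
  sm[is.na(sm)] <- profile[is.na(sm)]
  mid <- (max(sm) + min(sm)) / 2
  z0_init <- z[which.min(abs(sm - mid))]
  start <- list(
    b = min(profile), a = diff(range(profile)),
    z0 = z0_init, w = 2
  )
  w_lo <- 0.05
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a / (1 + exp(-(z - z0) / w)),
      data = data.frame(z = z, y = profile),
      start = start,
      lower = c(b = -Inf, a = 1e-12, z0 = -nz, w = w_lo),
      upper = c(b = Inf, a = Inf, z0 = 2 * nz, w = nz),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(b = NA_real_, a = NA_real_, z0 = NA_real_, w = NA_real_,
                  converged = FALSE))
  }
  p <- coef(fit)
  # a fit pinned at the upper width bound or with its centre outside the
  # profile has degenerated into a ramp through noise: count it as failed
  ok <- is.finite(p["w"]) && p["w"] >= w_lo && p["w"] < nz &&
    p["a"] > 0 && p["z0"] >= 0 && p["z0"] <= nz + 1
  tibble(b = unname(p["b"]), a = unname(p["a"]), z0 = unname(p["z0"]),
         w = unname(p["w"]), converged = ok)
}

#' Liver-lung edge width (LLE)
#'
#' Fits every line profile of the ROI with [fit_sigmoid_profile()] and
#' returns the mean fitted width over converged fits, in voxels, plus fit
#' bookkeeping. Larger LLE means a blurrier edge. Errors when fewer than half
#' the profiles converge. `width_scale = "tangent"` reports `4 w` (the width
#' of the tangent-line crossing of the logistic) instead of the logistic
#' scale `w`.
#'
#' @inheritParams compute_snr
#' @param width_scale `"logistic"` (default, reports the scale parameter `w`)
#'   or `"tangent"` (reports `4 w`).
#' @return A one-row tibble `lle_dbar`, `n_profiles_fit`, `fit_failures`.
#' @export
compute_lle <- function(volume, roi, width_scale = c("logistic", "tangent")) {
  width_scale <- rlang::arg_match(width_scale)
  profs <- extract_profiles(volume, roi)
  fits <- purrr::map_dfr(seq_len(ncol(profs)), function(j) fit_sigmoid_profile(profs[, j]))
  ok <- fits$converged
  if (sum(ok) < ncol(profs) / 2) {
    abort(sprintf("only %d of %d profiles converged (need >= 50%%).",
                  sum(ok), ncol(profs)))
  }
  dbar <- mean(fits$w[ok])
  if (width_scale == "tangent") dbar <- 4 * dbar
  tibble(lle_dbar = dbar, n_profiles_fit = sum(ok),
         fit_failures = sum(!ok))
}

#' Combined quantitative image quality
#'
#' @inheritParams compute_lle
#' @return A one-row tibble `snr`, `lle_dbar`, `n_profiles_fit`,
#'   `fit_failures`.
#' @examples
#' vol <- gen_phantom_volume(phantom_spec(noise_sd = 5, seed = 2))
#' compute_quality(vol, roi_spec())
#' @export
compute_quality <- function(volume, roi, width_scale = c("logistic", "tangent")) {
  lle <- compute_lle(volume, roi, width_scale)
  dplyr::bind_cols(tibble(snr = compute_snr(volume, roi)), lle)
}

#' Suggest liver/lung slice placement from the volume itself
#'
#' Helper for ROI placement: returns the ROI-internal z of the maximal mean
#' through-edge gradient plus liver/lung slices well to either side.
#'
#' @inheritParams compute_snr
#' @return A list `edge_z`, `liver_slice_z`, `lung_slice_z` (ROI-internal).
#' @export
suggest_slices <- function(volume, roi) {
  profs <- extract_profiles(volume, roi)
  mp <- rowMeans(profs)
  edge <- which.max(abs(diff(mp)))
  nz <- length(mp)
  liver <- if (mp[nz] > mp[1]) nz - 1L else 2L
  lung <- if (mp[nz] > mp[1]) 2L else nz - 1L
  list(edge_z = edge, liver_slice_z = liver, lung_slice_z = lung)
}
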