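test_that("ROI specification is validated", {
  expect_error(roi_spec(liver_slice_z = 5, lung_slice_z = 5), "differ")
  expect_error(roi_spec(liver_slice_z = 31), "inside")
  expect_error(roi_spec(size = c(10, 10)), "length-3")
  vol <- gen_phantom_volume(phantom_spec(shape = c(6, 6, 20, 2)))
  expect_error(compute_snr(vol, roi_spec(origin = c(1, 1, 1))), "bounds")
})

test_that("SNR is liver mean over lung SD, with sensible scaling behaviour", {
  # hand-built volume: liver slice constant, lung slice pure noise
  set.seed(31)
  arr <- array(0, dim = c(10, 10, 30, 4))
  arr[, , 25:30, ] <- 100
  arr[, , 1:6, ] <- rnorm(10 * 10 * 6 * 4, sd = 10)
  roi <- roi_spec(liver_slice_z = 28, lung_slice_z = 3)
  snr <- compute_snr(arr, roi)
  expect_equal(snr, 10, tolerance = 0.05)

  # scaling the whole image leaves SNR unchanged; scaling signal only doubles it
  expect_equal(compute_snr(arr * 2, roi), snr)
  arr2 <- arr
  arr2[, , 25:30, ] <- 200
  expect_equal(compute_snr(arr2, roi), 2 * snr, tolerance = 1e-12)

  # noise-free lung slice gives the infinity sentinel, not an error
  clean <- array(rep(logistic_profile(), each = 100), dim = c(10, 10, 30, 1))
  expect_identical(compute_snr(clean, roi_spec()), Inf)
})

test_that("profile extraction yields one time-averaged profile per in-plane voxel", {
  vol <- gen_phantom_volume(phantom_spec(noise_sd = 0, seed = 2))
  profs <- extract_profiles(vol, roi_spec())
  expect_identical(dim(profs), c(30L, 100L))
  expect_true(all(apply(profs, 1, function(r) diff(range(r)) == 0))) # identical
  small <- extract_profiles(vol, roi_spec(size = c(5, 5, 30)))
  expect_identical(ncol(small), 25L)
  degen <- structure(list(origin = c(1L, 1L, 1L), size = c(5L, 5L, 1L),
                          liver_slice_z = 1L, lung_slice_z = 1L),
                     class = "roi_spec")
  expect_error(extract_profiles(vol, degen), "degenerate")
})

test_that("sigmoid fits recover exact logistic parameters to high precision", {
  fit <- fit_sigmoid_profile(logistic_profile(30, b = 0, a = 100, z0 = 15, w = 2))
  expect_true(fit$converged)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(fit$a, 100, tolerance = 1e-5)
  expect_equal(fit$z0, 15, tolerance = 1e-6)
  expect_equal(fit$w, 2, tolerance = 1e-6)
})

test_that("sigmoid width survives noise on average and collapses on step edges", {
  set.seed(41)
  ws <- replicate(100, {
    p <- logistic_profile(30, 0, 100, 15, 2) + rnorm(30, sd = 5)
    f <- fit_sigmoid_profile(p)
    if (f$converged) f$w else NA_real_
  })
  expect_equal(mean(ws, na.rm = TRUE), 2, tolerance = 0.1) # +/- 0.2 voxel

  step <- c(rep(0, 15), rep(100, 15))
  fs <- fit_sigmoid_profile(step)
  expect_true(fs$converged)
  expect_lte(fs$w, 0.5)

  flat <- fit_sigmoid_profile(rep(5, 30))
  expect_false(flat$converged)
  expect_error(fit_sigmoid_profile(1:4), "5 points")
})

test_that("LLE equals the true width on clean phantoms and counts failures", {
  vol <- gen_phantom_volume(phantom_spec(noise_sd = 0, edge_width_w = 2))
  q <- compute_lle(vol, roi_spec())
  expect_equal(q$lle_dbar, 2, tolerance = 1e-6)
  expect_identical(q$n_profiles_fit + q$fit_failures, 100L)
  expect_identical(q$fit_failures, 0L)
  # tangent-width convention reports 4w
  q4 <- compute_lle(vol, roi_spec(), width_scale = "tangent")
  expect_equal(q4$lle_dbar, 8, tolerance = 1e-6)
})

test_that("LLE is invariant to global intensity scaling and offset", {
  vol <- gen_phantom_volume(phantom_spec(noise_sd = 5, seed = 6))
  roi <- roi_spec()
  base <- compute_lle(vol, roi)$lle_dbar
  scaled <- vol
  scaled$data <- 3 * vol$data + 50
  expect_equal(compute_lle(scaled, roi)$lle_dbar, base, tolerance = 1e-4)
})

test_that("width recovery holds across a width x SNR grid", {
  cells <- expand.grid(w = c(1, 2, 4), snr = c(5, 20))
  errs <- mapply(function(w, snr) {
    vol <- gen_phantom_volume(phantom_spec(
      edge_width_w = w, noise_sd = 100 / snr, shape = c(10, 10, 30, 3),
      seed = round(1000 * w + snr)
    ))
    abs(compute_lle(vol, roi_spec())$lle_dbar - w)
  }, cells$w, cells$snr)
  expect_lte(median(errs), 0.25)
})

test_that("slice suggestion finds the edge and sides of a clean phantom", {
  vol <- gen_phantom_volume(phantom_spec(noise_sd = 0, edge_z0 = 15))
  sug <- suggest_slices(vol, roi_spec())
  expect_true(sug$edge_z %in% 14:15) # steepest rise brackets the edge centre
  expect_identical(sug$liver_slice_z, 29L) # liver bright at high z
  expect_identical(sug$lung_slice_z, 2L)
})

test_that("combined quality output carries both metrics", {
  vol <- gen_phantom_volume(phantom_spec(noise_sd = 8, seed = 3))
  q <- compute_quality(vol, roi_spec(liver_slice_z = 29, lung_slice_z = 2))
  expect_named(q, c("snr", "lle_dbar", "n_profiles_fit", "fit_failures"))
  expect_gt(q$snr, 0)
  expect_gt(q$lle_dbar, 0)
})
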