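test_that("spec invariants reject impossible geometry", {
  expect_error(mouse_spec_bad <- phantom_spec(
    "uniform-cylinder", diameter_mm = 60, length_mm = 10,
    activity_concentration = 1,
    grid = list(n_x = 90, n_y = 90, n_slices = 1, voxel_mm = 0.5)),
    "extent error")
  expect_error(phantom_spec(
    "cylinder-with-hot-sphere", diameter_mm = 50, length_mm = 10,
    activity_concentration = 1, sphere_center_mm = c(22, 0, 0),
    sphere_radius_mm = 6, sphere_to_background_ratio = 4),
    "geometry error")
  expect_error(phantom_spec(
    "cylinder-with-hot-sphere", diameter_mm = 50, length_mm = 10,
    activity_concentration = 1, sphere_center_mm = c(0, 0, 0),
    sphere_radius_mm = 6, sphere_to_background_ratio = 0.5),
    "ratio")
  expect_error(phantom_spec("uniform-cylinder", 30, 10,
                            activity_concentration = -1),
    "activity_concentration")
})

test_that("mouse phantom is water at the cylinder centre and zero outside", {
  ph <- make_phantom(mouse2d())
  d <- dim(ph$mu$values)
  expect_equal(ph$mu$values[d[1] %/% 2, d[2] %/% 2, 1], 0.0969)
  expect_equal(ph$mu$values[1, 1, 1], 0)
  expect_equal(ph$activity$values[1, 1, 1], 0)
  # mu-map support equals activity support for uniform phantoms
  expect_identical(ph$mu$values > 0, ph$activity$values > 0)
})

test_that("zero concentration gives an identically zero activity image", {
  spec <- phantom_spec("uniform-cylinder", 30, 45, activity_concentration = 0,
                       grid = list(n_x = 60, n_y = 60, n_slices = 1,
                                   voxel_mm = 0.6))
  expect_true(all(make_phantom(spec)$activity$values == 0))
})

test_that("anti-aliased disk area matches the analytic area within 0.5%", {
  ph <- make_phantom(mouse2d())
  per_slice_area <- sum(ph$activity$values[, , 1]) *
    prod(ph$activity$spacing[1:2])          # conc = 1 MBq/cc
  expect_equal(per_slice_area, pi * 15^2, tolerance = 0.005)
})

test_that("rasterized area error shrinks at least linearly with voxel size", {
  area_err <- function(voxel_mm, n) {
    spec <- phantom_spec("uniform-cylinder", 30, 45,
                         activity_concentration = 1,
                         grid = list(n_x = n, n_y = n, n_slices = 1,
                                     voxel_mm = voxel_mm))
    a <- sum(make_phantom(spec)$activity$values) * voxel_mm^2
    abs(a - pi * 15^2)
  }
  e_coarse <- area_err(1.0, 45L)
  e_fine <- area_err(0.5, 90L)
  expect_lt(e_fine, e_coarse / 2 + 1e-9)
})

test_that("hot sphere scales the background by the requested ratio", {
  spec <- hot_sphere_phantom()
  ph <- make_phantom(spec)
  sph_mean <- roi_mean(ph$activity, spec$sphere_center_mm,
                       0.7 * spec$sphere_radius_mm, "sphere")
  bkg_mean <- roi_mean(ph$activity, c(-10, 0), 6)
  expect_equal(sph_mean / bkg_mean, 4, tolerance = 0.01)
  expect_equal(sph_mean, 2.0, tolerance = 0.01)   # 0.5 MBq/cc background x 4
  # sphere volume from the rasterized excess activity
  excess <- sum(ph$activity$values -
                  make_phantom(rat_phantom(n_slices = spec$grid$n_slices))$activity$values)
  vol <- excess * prod(ph$activity$spacing) / (0.5 * 3)  # (ratio-1)*conc
  expect_equal(vol, 4 / 3 * pi * 6^3, tolerance = 0.02)
})

test_that("add_hot_sphere with ratio 1 is the identity", {
  spec <- hot_sphere_phantom(n_slices = 1L)
  ph <- make_phantom(rat_phantom(n_slices = 1L))
  spec1 <- spec; spec1$sphere_to_background_ratio <- 1
  expect_identical(add_hot_sphere(ph$activity, spec1)$values,
                   ph$activity$values)
  hot <- add_hot_sphere(ph$activity, spec)
  inside <- roi_mean(hot, spec$sphere_center_mm[1:2],
                     0.7 * spec$sphere_radius_mm)
  expect_equal(inside / 0.5, 4, tolerance = 0.01)
})

test_that("phantom generation is deterministic", {
  a <- make_phantom(hot_sphere_phantom(n_slices = 2L))
  b <- make_phantom(hot_sphere_phantom(n_slices = 2L))
  expect_identical(a$activity$values, b$activity$values)
  expect_identical(a$mu$values, b$mu$values)
})

test_that("synthetic CT inverts the calibration exactly at zero noise", {
  curve <- default_calibration()
  mu <- make_phantom(mouse2d())$mu
  ct <- make_synthetic_ct(mu, curve, noise_sd_hu = 0)
  expect_equal(max(abs(hu_to_mu(ct, curve)$values - mu$values)), 0,
               tolerance = 1e-6)
  # mu equal to the curve value at HU = 0 maps back to HU = 0
  flat <- voxel_image(array(curve$a3, c(4, 4, 1)), 1, role = "mu")
  expect_equal(max(abs(make_synthetic_ct(flat, curve)$values)), 0,
               tolerance = 1e-9)
  # unattainable mu is a domain error
  hi <- voxel_image(array(0.5, c(2, 2, 1)), 1, role = "mu")
  expect_error(make_synthetic_ct(hi, curve), "domain error")
})

test_that("synthetic CT noise is seeded and reproducible", {
  curve <- default_calibration()
  mu <- make_phantom(mouse2d())$mu
  a <- make_synthetic_ct(mu, curve, noise_sd_hu = 25, seed = 11)
  b <- make_synthetic_ct(mu, curve, noise_sd_hu = 25, seed = 11)
  c <- make_synthetic_ct(mu, curve, noise_sd_hu = 25, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("phantom specs round-trip through the text configuration", {
  spec <- hot_sphere_phantom(n_slices = 2L)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(spec), path)
  back <- read_phantom_spec(path)
  expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
})
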