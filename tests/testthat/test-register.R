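test_that("rigid transforms validate and compose correctly", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "proper")
  t1 <- inplane_transform(30, c(5, -3, 2))
  t2 <- inplane_transform(-12, c(0, 1, 0))
  p <- matrix(rnorm(15), 5, 3)
  expect_equal(transform_points(compose_transform(t1, t2), p),
               transform_points(t1, transform_points(t2, p)),
               tolerance = 1e-12)
  # compose with inverse is the identity within 1e-10
  id <- compose_transform(t1, invert_transform(t1))
  expect_lt(max(abs(id$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(id$translation_mm)), 1e-10)
  h <- as_homogeneous(t1)
  expect_equal(h[1:3, 4], t1$translation_mm)
})

test_that("rigid estimation recovers a known transform exactly", {
  set.seed(8)
  pts <- matrix(runif(12, -20, 20), 4, 3)
  truth <- inplane_transform(30, c(5, -3, 2))
  moved <- transform_points(truth, pts)
  est <- estimate_rigid(pts, moved)
  expect_lt(max(abs(est$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(est$translation_mm - truth$translation_mm)), 1e-9)
  expect_lt(attr(est, "rms_residual_mm"), 1e-9)
  # identical point sets give the identity
  est_id <- estimate_rigid(pts, pts)
  expect_lt(max(abs(est_id$rotation - diag(3))), 1e-10)
})

test_that("degenerate and reflected configurations are caught", {
  line <- cbind(1:4, 2 * (1:4), 0)
  expect_error(estimate_rigid(line, line), "collinear")
  expect_error(estimate_rigid(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               "at least 3")
  # a strongly chiral configuration: its mirror image cannot be matched
  # by any proper rotation
  pts <- rbind(c(20, 0, 0), c(0, 20, 0), c(0, 0, 20), c(0, 0, 0))
  mirrored <- pts %*% diag(c(-1, 1, 1))
  est <- estimate_rigid(pts, mirrored)
  expect_gt(attr(est, "rms_residual_mm"), 1)
  expect_equal(det(est$rotation), 1, tolerance = 1e-9)
})

test_that("fiducial detection finds blob centroids to subvoxel accuracy", {
  n <- 60L
  img <- voxel_image(array(0, c(n, n, 3)), spacing = c(1, 1, 2))
  centers <- rbind(c(-15.5, -10, 0), c(12, -14, 0), c(8, 18, 0))
  peak <- c(30, 20, 10)
  P <- petac:::voxel_center_grid(img)
  for (i in 1:3) {
    d2 <- rowSums(sweep(P, 2, centers[i, ])^2)
    img$values <- img$values + array(peak[i] * exp(-d2 / (2 * 2^2)), dim(img$values))
  }
  found <- detect_fiducials(img, intensity_threshold_fraction = 0.03)
  expect_equal(nrow(found), 3L)
  # sorted by intensity: brightest first; centroids within half a voxel
  for (i in 1:3)
    expect_lt(sqrt(sum((found[i, ] - centers[i, ])^2)), 0.5)
})

test_that("blank images and single centred blobs behave as documented", {
  blank <- voxel_image(array(0, c(20, 20, 1)), 1)
  expect_equal(nrow(detect_fiducials(blank)), 0L)
  one <- voxel_image(array(0, c(21, 21, 1)), 1)
  one$values[11, 11, 1] <- 5          # single voxel at a voxel centre
  one$values[10:12, 11, 1] <- c(2, 5, 2)
  one$values[11, 10:12, 1] <- c(2, 5, 2)
  found <- detect_fiducials(one, 0.1, min_voxels = 1L)
  expect_equal(nrow(found), 1L)
  expect_equal(found[1, 1:2], petac:::voxel_center_grid(one)[11 + 10 * 21, 1:2],
               tolerance = 1e-12)
})

test_that("the body component is excluded only when it dwarfs the beads", {
  n <- 80L
  img <- voxel_image(array(0, c(n, n, 1)), 1)
  P <- petac:::voxel_center_grid(img)
  body <- rowSums(P[, 1:2]^2) <= 20^2
  img$values[array(body, dim(img$values))] <- 1
  for (ctr in list(c(30, 0, 0), c(-25, 20, 0))) {
    d2 <- rowSums(sweep(P, 2, ctr)^2)
    img$values <- img$values + array(10 * (d2 <= 2^2), dim(img$values))
  }
  found <- detect_fiducials(img, intensity_threshold_fraction = 0.05)
  expect_equal(nrow(found), 2L)   # the big dim body is dropped, beads kept
})

test_that("resampling through the identity is bitwise lossless", {
  set.seed(4)
  img <- voxel_image(array(runif(30 * 30 * 3), c(30, 30, 3)),
                     spacing = c(1, 1, 2))
  out <- resample(img, rigid_transform(), img)
  expect_identical(out$values, img$values)
})

test_that("translation by whole voxels shifts the array exactly", {
  set.seed(5)
  img <- voxel_image(array(runif(24 * 24), c(24, 24, 1)), spacing = 0.5)
  t <- rigid_transform(diag(3), c(3 * 0.5, -2 * 0.5, 0))   # 3, -2 voxels
  out <- resample(img, t, img)
  expect_equal(out$values[8:20, 8:20, 1], img$values[(8:20) - 3, (8:20) + 2, 1],
               tolerance = 1e-12)
})

test_that("rotation conserves interior mass within 1%", {
  ph <- make_phantom(mouse_phantom(n_slices = 3L))
  t <- inplane_transform(25, c(1.2, -0.7, 0))
  out <- resample(ph$mu, t, ph$mu)
  expect_equal(sum(out$values), sum(ph$mu$values), tolerance = 0.01)
})

test_that("fiducial realignment reproduces the unshifted ACFs within 1%", {
  geom <- sinogram_geometry()
  spec <- rat_phantom(fiducials = default_fiducials(50), n_slices = 3L)
  truth <- default_ct_offset()
  mu_pet <- make_phantom(spec)$mu
  mu_ct <- make_phantom(spec,
    point_map = function(P) transform_points(truth, P))$mu
  act_ct <- make_phantom(spec,
    point_map = function(P) transform_points(truth, P))$activity
  fid_fixed <- detect_fiducials(make_phantom(spec)$activity)
  fid_moving <- detect_fiducials(act_ct)
  est <- estimate_rigid(fid_moving[1:3, ], fid_fixed[1:3, ])
  realigned <- resample(mu_ct, est, mu_pet)
  acf_ref <- acf_sinogram(mu_pet, geom)
  acf_re <- acf_sinogram(realigned, geom)
  sel <- acf_ref$values > 1.05
  expect_lt(max(abs(acf_re$values[sel] / acf_ref$values[sel] - 1)), 0.01)
})
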