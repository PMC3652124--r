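test_that("precorrection undoes attenuation exactly in the sinogram domain", {
  geom <- small_geom()
  ph <- make_phantom(rat_phantom(n_slices = 1L))
  att <- attenuated_forward(ph$activity, ph$mu, geom)
  acf <- acf_sinogram(ph$mu, geom)
  p <- radon_forward(ph$activity, geom)
  pc <- precorrect(att, acf)
  expect_equal(max(abs(pc$values - p$values) / pmax(p$values, 1e-12)), 0,
               tolerance = 1e-10)
  expect_identical(pc$kind, "line-integral")
  # unit ACF is the identity
  ones <- sinogram(array(1, dim(att$values)), geom, kind = "acf")
  expect_equal(precorrect(att, ones)$values, att$values, tolerance = 1e-15)
  # rat central bin is boosted by ~1.623
  cen <- (geom$n_bins + 1L) / 2
  expect_equal(pc$values[1, cen, 1] / att$values[1, cen, 1],
               exp(0.0969 * 5), tolerance = 0.005)
  # a non-ACF second argument is a kind error
  expect_error(precorrect(att, p), "kind mismatch")
})

test_that("OSEM recovers a uniform disk to within 2% in the interior", {
  geom <- sinogram_geometry()
  disk <- unit_disk(25)
  p <- radon_forward(disk, geom)
  rec <- osem_reconstruct(p, disk, recon_config(8L, 10L, ac_mode = "none"))
  xs <- voxel_centers(disk, 1)
  interior <- outer(xs^2, xs^2, "+") <= 20^2
  vals <- rec$values[, , 1][interior]
  expect_lt(max(abs(vals - 1)), 0.02)
  expect_true(all(rec$values >= 0))
})

test_that("an all-zero sinogram reconstructs to an all-zero image", {
  g <- small_geom()
  z <- sinogram(array(0, c(g$n_angles, g$n_bins, 1)), g, kind = "counts")
  rec <- osem_reconstruct(z, recon_grid(40, 40, 1),
                          recon_config(4L, 2L, ac_mode = "none"))
  expect_true(all(rec$values == 0))
})

test_that("reprojected reconstruction matches noiseless data at convergence", {
  geom <- small_geom()
  ph <- make_phantom(mouse_phantom(n_slices = 1L))
  p <- radon_forward(ph$activity, geom)
  rec <- osem_reconstruct(p, ph$activity,
                          recon_config(6L, 15L, ac_mode = "none"))
  reproj <- radon_forward(rec, geom)
  expect_lt(abs(sum(reproj$values) - sum(p$values)) / sum(p$values), 0.01)
})

test_that("OSEM with one subset is exactly MLEM", {
  geom <- sinogram_geometry(n_angles = 24L, n_bins = 41L, bin_width_mm = 1)
  disk <- unit_disk(12, n = 36L, voxel_mm = 1)
  counts <- poisson_sample(radon_forward(disk, geom), 2e5, seed = 3)
  # MLEM reference: hand-rolled multiplicative EM on the same system matrix
  A <- radon_matrix(geom, 36L, 36L, 1)
  y <- as.numeric(t(counts$values[, , 1]))
  sens <- as.numeric(Matrix::crossprod(A, rep(1, length(y))))
  ctr <- ((1:36) - 18.5) * 1
  mask <- sens > 0 & as.vector(outer(ctr^2, ctr^2, "+") <= (geom$fov_mm / 2)^2)
  x <- ifelse(mask, 1, 0)
  for (it in 1:5) {
    yhat <- as.numeric(A %*% x)
    ratio <- ifelse(yhat > 0, y / yhat, 0)
    upd <- as.numeric(Matrix::crossprod(A, ratio))
    x[mask] <- x[mask] * upd[mask] / sens[mask]
  }
  rec <- osem_reconstruct(counts, recon_grid(36, 36, 1),
                          recon_config(1L, 5L, ac_mode = "none"))
  expect_equal(as.numeric(rec$values[, , 1]), x, tolerance = 1e-12)
})

test_that("MLEM does not decrease the Poisson likelihood of noiseless data", {
  geom <- sinogram_geometry(n_angles = 24L, n_bins = 41L, bin_width_mm = 1)
  disk <- unit_disk(12, n = 36L, voxel_mm = 1)
  p <- radon_forward(disk, geom)
  ll <- numeric(6)
  for (k in seq_along(ll)) {
    rec <- osem_reconstruct(p, disk, recon_config(1L, k, ac_mode = "none"))
    ll[k] <- petac:::poisson_loglik(p, rec)
  }
  expect_true(all(diff(ll) > -1e-7 * abs(ll[-length(ll)])))
})

test_that("system-matrix attenuation equals sinogram precorrection on noiseless data", {
  geom <- small_geom()
  ph <- make_phantom(mouse_phantom(n_slices = 1L))
  att <- attenuated_forward(ph$activity, ph$mu, geom)
  acf <- acf_sinogram(ph$mu, geom)
  rec_pre <- osem_reconstruct(precorrect(att, acf), ph$activity,
                              recon_config(6L, 8L, ac_mode = "precorrected"))
  rec_sys <- osem_reconstruct(att, ph$activity,
                              recon_config(6L, 8L, ac_mode = "system-matrix"),
                              acf = acf)
  xs <- voxel_centers(ph$activity, 1)
  interior <- outer(xs^2, xs^2, "+") <= 12^2
  a <- rec_pre$values[, , 1][interior]; b <- rec_sys$values[, , 1][interior]
  expect_equal(a, b, tolerance = 0.02)
  expect_error(osem_reconstruct(att, ph$activity,
                                recon_config(6L, 1L, ac_mode = "system-matrix")),
               "requires an ACF")
})

test_that("correcting attenuation raises the central count density", {
  geom <- small_geom()
  ph <- make_phantom(mouse_phantom(n_slices = 1L))
  att <- attenuated_forward(ph$activity, ph$mu, geom)
  acf <- acf_sinogram(ph$mu, geom)
  cfg <- recon_config(6L, 8L, ac_mode = "none")
  rec_nc <- osem_reconstruct(att, ph$activity, cfg)
  rec_ac <- osem_reconstruct(precorrect(att, acf), ph$activity, cfg)
  expect_gt(roi_mean(rec_ac, c(0, 0), 7.5), roi_mean(rec_nc, c(0, 0), 7.5))
})

test_that("subset count must divide the number of angles", {
  g <- sinogram_geometry(n_angles = 30L, n_bins = 21L, bin_width_mm = 2)
  s <- sinogram(array(1, c(30, 21, 1)), g)
  expect_error(osem_reconstruct(s, recon_grid(20, 20, 2),
                                recon_config(8L, 1L, ac_mode = "none")),
               "divisible")
})
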