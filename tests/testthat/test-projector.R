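test_that("forward projection of a zero image is zero", {
  img <- voxel_image(array(0, c(40, 40, 2)), spacing = 1)
  s <- radon_forward(img, small_geom())
  expect_true(all(s$values == 0))
})

test_that("central-bin projection of a uniform disk equals the diameter", {
  disk <- unit_disk(radius_mm = 25)
  geom <- sinogram_geometry()
  p <- radon_forward(disk, geom)
  cen <- (geom$n_bins + 1L) / 2
  # chord through the centre is 2R at every angle
  expect_equal(mean(p$values[, cen, 1]), 50, tolerance = 0.005)
  expect_true(all(abs(p$values[, cen, 1] / 50 - 1) < 0.005))
  # off-centre bins follow the closed-form chord 2*sqrt(R^2 - s^2)
  s <- (seq_len(geom$n_bins) - (geom$n_bins + 1) / 2) * geom$bin_width_mm
  sel <- abs(s) <= 20
  chord <- 2 * sqrt(25^2 - s[sel]^2)
  err <- abs(sweep(p$values[1, sel, 1, drop = FALSE], 2, chord, "/") - 1)
  expect_lt(max(err), 0.006)
})

test_that("projections of a circularly symmetric image are angle-invariant", {
  # an isotropic Gaussian whose tails vanish well inside the square image,
  # so every angle sees the same mass
  n <- 120L; sig <- 6
  xs <- ((seq_len(n)) - (n + 1) / 2) * 0.5
  r2 <- outer(xs^2, xs^2, "+")
  img <- voxel_image(array(exp(-r2 / (2 * sig^2)), c(n, n, 1)), spacing = 0.5)
  geom <- sinogram_geometry()
  p <- radon_forward(img, geom)
  s <- (seq_len(geom$n_bins) - (geom$n_bins + 1) / 2) * geom$bin_width_mm
  rows <- p$values[, abs(s) <= 15, 1]
  spread <- apply(rows, 2, function(col) (max(col) - min(col)) / mean(col))
  expect_lt(max(spread), 0.005)
  # and they match the closed-form Radon transform of a Gaussian
  cf <- sig * sqrt(2 * pi) * exp(-s^2 / (2 * sig^2))
  sel <- abs(s) <= 12
  err <- abs(sweep(p$values[, sel, 1], 2, cf[sel], "/") - 1)
  expect_lt(max(err), 0.005)
})

test_that("radon_forward is linear in the image", {
  set.seed(3)
  g <- small_geom()
  a <- voxel_image(array(runif(40 * 40), c(40, 40, 1)), spacing = 1)
  b <- voxel_image(array(runif(40 * 40), c(40, 40, 1)), spacing = 1)
  ab <- voxel_image(2 * a$values + 3 * b$values, spacing = 1)
  expect_equal(radon_forward(ab, g)$values,
               2 * radon_forward(a, g)$values + 3 * radon_forward(b, g)$values,
               tolerance = 1e-12)
})

test_that("objects outside the radial field of view are rejected", {
  g <- sinogram_geometry(n_angles = 30L, n_bins = 21L, bin_width_mm = 1)
  vals <- array(0, c(60, 60, 1))
  vals[2, 30, 1] <- 1        # ~28 mm from centre, FOV radius 10.5 mm
  img <- voxel_image(vals, spacing = 1)
  expect_error(radon_forward(img, g), "truncation")
})

test_that("ACF sinograms match the closed-form water-cylinder factors", {
  geom <- sinogram_geometry()
  cen <- (geom$n_bins + 1L) / 2
  # empty attenuator: ACF identically 1
  empty <- voxel_image(array(0, c(50, 50, 1)), spacing = 1, role = "mu")
  expect_true(all(acf_sinogram(empty, geom)$values == 1))
  # rat-sized: exp(0.0969/cm x 5 cm), mouse-sized: exp(0.0969 x 3)
  acf_rat <- acf_sinogram(water_disk_mu(25), geom)
  expect_equal(mean(acf_rat$values[, cen, 1]), exp(0.0969 * 5),
               tolerance = 0.005)
  acf_mouse <- acf_sinogram(water_disk_mu(15, n = 80L), geom)
  expect_equal(mean(acf_mouse$values[, cen, 1]), exp(0.0969 * 3),
               tolerance = 0.005)
  expect_true(all(acf_rat$values >= 1))
})

test_that("ACF of a sum of attenuation maps is the product of ACFs", {
  g <- small_geom()
  mu1 <- water_disk_mu(10, n = 60L, voxel_mm = 1, mu = 0.05)
  mu2 <- water_disk_mu(18, n = 60L, voxel_mm = 1, mu = 0.08)
  both <- voxel_image(mu1$values + mu2$values, mu1$spacing, mu1$origin,
                      role = "mu")
  expect_equal(acf_sinogram(both, g)$values,
               acf_sinogram(mu1, g)$values * acf_sinogram(mu2, g)$values,
               tolerance = 1e-10)
})

test_that("attenuated forward equals unattenuated forward over the ACF", {
  geom <- small_geom()
  ph <- make_phantom(rat_phantom(n_slices = 1L))
  att <- attenuated_forward(ph$activity, ph$mu, geom)
  p <- radon_forward(ph$activity, geom)
  acf <- acf_sinogram(ph$mu, geom)
  expect_equal(max(abs(att$values * acf$values - p$values) /
                     pmax(p$values, 1e-12)), 0, tolerance = 1e-10)
  # mu = 0 leaves the projection untouched
  zero_mu <- voxel_image(array(0, dim(ph$mu$values)), ph$mu$spacing,
                         ph$mu$origin, role = "mu")
  expect_equal(attenuated_forward(ph$activity, zero_mu, geom)$values,
               p$values, tolerance = 1e-12)
  # rat central bin is damped by exp(-0.4845)
  cen <- (geom$n_bins + 1L) / 2
  expect_equal(att$values[1, cen, 1] / p$values[1, cen, 1],
               exp(-0.0969 * 5), tolerance = 0.005)
  # grid mismatch is a shape error
  other <- make_phantom(mouse_phantom(n_slices = 1L))$mu
  expect_error(attenuated_forward(ph$activity, other, geom), "shape error")
})

test_that("forward and backprojection are exact adjoints", {
  set.seed(11)
  g <- small_geom()
  for (rep in 1:3) {
    x <- voxel_image(array(runif(30 * 30), c(30, 30, 1)), spacing = 1.2)
    y <- sinogram(array(runif(g$n_angles * g$n_bins),
                        c(g$n_angles, g$n_bins, 1)), g)
    Ax <- radon_forward(x, g)
    Aty <- radon_backward(y, x)
    lhs <- sum(Ax$values * y$values)
    rhs <- sum(x$values * Aty$values)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("Poisson sampling preserves expected totals and is seeded", {
  geom <- small_geom()
  disk <- unit_disk(20, n = 50L, voxel_mm = 1)
  s <- radon_forward(disk, geom)
  n_tot <- 5e5
  c1 <- poisson_sample(s, n_tot, seed = 5)
  c2 <- poisson_sample(s, n_tot, seed = 5)
  c3 <- poisson_sample(s, n_tot, seed = 6)
  expect_identical(c1$values, c2$values)
  expect_false(identical(c1$values, c3$values))
  expect_identical(c1$kind, "counts")
  # total within 3 sigma = 3 sqrt(N)
  expect_lt(abs(sum(c1$values) - n_tot), 3 * sqrt(n_tot))
  # zero sinogram stays zero
  z <- sinogram(array(0, dim(s$values)), geom)
  expect_true(all(poisson_sample(z, 100, seed = 1)$values == 0))
  # negative mu rejected by acf_sinogram
  neg <- voxel_image(array(0, c(10, 10, 1)), 1)
  neg$values[5, 5, 1] <- -1
  expect_error(acf_sinogram(neg, geom), "nonnegative")
})
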