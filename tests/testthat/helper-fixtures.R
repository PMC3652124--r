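# Small shared fixtures; system matrices are cached inside the package, so
# repeated projections of the same geometry cost one build.

small_geom <- function() sinogram_geometry(n_angles = 60L, n_bins = 81L,
                                           bin_width_mm = 1)

# anti-aliased unit disk image (single slice), centred
unit_disk <- function(radius_mm = 25, n = 120L, voxel_mm = 0.5) {
  spec <- phantom_spec("uniform-cylinder", diameter_mm = 2 * radius_mm,
                       length_mm = 100, activity_concentration = 1,
                       material_mu = 0,
                       grid = list(n_x = n, n_y = n, n_slices = 1L,
                                   voxel_mm = voxel_mm, slice_mm = voxel_mm))
  make_phantom(spec)$activity
}

water_disk_mu <- function(radius_mm = 25, n = 120L, voxel_mm = 0.5,
                          mu = 0.0969) {
  d <- unit_disk(radius_mm, n, voxel_mm)
  voxel_image(d$values * mu, d$spacing, d$origin, role = "mu")
}

rat2d <- function() rat_phantom(n_slices = 1L)
mouse2d <- function() mouse_phantom(n_slices = 1L)
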