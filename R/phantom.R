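#' Parametric phantom description
#'
#' Describes the cylindrical phantoms used to study attenuation at the
#' preclinical scale: a water-equivalent cylinder (mouse- or rat-sized),
#' optionally with a hot sphere (lesion surrogate) and with high-activity
#' fiducial beads placed around the body for coregistration. All lengths are
#' mm, activity concentrations MBq/cc, attenuation coefficients 1/cm at
#' 511 keV.
#'
#' @param kind `"uniform-cylinder"` or `"cylinder-with-hot-sphere"`.
#' @param diameter_mm cylinder diameter.
#' @param length_mm cylinder length along z.
#' @param activity_concentration background activity concentration (MBq/cc).
#' @param material_mu attenuation coefficient of the fill material (1/cm);
#'   default water at 511 keV, 0.0969.
#' @param sphere_center_mm,sphere_radius_mm hot-sphere placement (mm), only
#'   for `kind = "cylinder-with-hot-sphere"`.
#' @param sphere_to_background_ratio sphere:background activity ratio
#'   (>= 1; hot inserts only).
#' @param fiducials list of fiducial beads, each a list with `center_mm`
#'   (3-vector), `radius_mm`, `concentration` (MBq/cc) and optionally `mu`
#'   (1/cm, default 0.17, zeolite-like). Give beads distinct concentrations
#'   and matching mu ordering so rank-based correspondence works.
#' @param grid list with `n_x`, `n_y`, `n_slices`, `voxel_mm` (in-plane) and
#'   `slice_mm` (axial spacing).
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [mouse_phantom()], [rat_phantom()]
#' @export
phantom_spec <- function(kind = c("uniform-cylinder", "cylinder-with-hot-sphere"),
                         diameter_mm, length_mm,
                         activity_concentration,
                         material_mu = 0.0969,
                         sphere_center_mm = NULL, sphere_radius_mm = NULL,
                         sphere_to_background_ratio = NULL,
                         fiducials = NULL,
                         grid = list(n_x = 140L, n_y = 140L, n_slices = 5L,
                                     voxel_mm = 0.5, slice_mm = 2)) {
  kind <- match.arg(kind)
  stopifnot(diameter_mm > 0, length_mm > 0)
  if (activity_concentration < 0)
    stop("'activity_concentration' must be >= 0")
  if (material_mu < 0) stop("'material_mu' must be >= 0")
  grid$n_x <- as.integer(grid$n_x); grid$n_y <- as.integer(grid$n_y)
  grid$n_slices <- as.integer(grid$n_slices)
  if (is.null(grid$slice_mm)) grid$slice_mm <- grid$voxel_mm
  extent <- c(grid$n_x, grid$n_y) * grid$voxel_mm
  if (diameter_mm > min(extent))
    stop(sprintf("extent error: %.1f mm cylinder does not fit in %.1f x %.1f mm grid",
                 diameter_mm, extent[1], extent[2]))
  if (kind == "cylinder-with-hot-sphere") {
    if (is.null(sphere_center_mm) || is.null(sphere_radius_mm) ||
        is.null(sphere_to_background_ratio))
      stop("hot-sphere phantoms need sphere_center_mm, sphere_radius_mm and sphere_to_background_ratio")
    if (sphere_to_background_ratio < 1)
      stop("'sphere_to_background_ratio' must be >= 1 (hot inserts only)")
    r_in <- sqrt(sum(sphere_center_mm[1:2]^2)) + sphere_radius_mm
    if (r_in >= diameter_mm / 2)
      stop("geometry error: hot sphere must lie strictly inside the cylinder")
  }
  if (!is.null(fiducials)) {
    fiducials <- lapply(fiducials, function(f) {
      if (is.null(f$mu)) f$mu <- 0.17
      stopifnot(length(f$center_mm) == 3L, f$radius_mm > 0,
                f$concentration >= 0, f$mu >= 0)
      f
    })
  }
  structure(list(kind = kind, diameter_mm = diameter_mm,
                 length_mm = length_mm,
                 activity_concentration = activity_concentration,
                 material_mu = material_mu,
                 sphere_center_mm = sphere_center_mm,
                 sphere_radius_mm = sphere_radius_mm,
                 sphere_to_background_ratio = sphere_to_background_ratio,
                 fiducials = fiducials, grid = grid),
            class = "phantom_spec")
}

#' Reference phantom specifications
#'
#' Ready-made specifications for the three phantom studies the package
#' models: a 30 mm diameter mouse-sized syringe filled uniformly at about
#' 1 MBq/cc, a 50 mm diameter, 80 mm long rat-sized cylinder at about
#' 0.5 MBq/cc, and the same rat cylinder with a hot sphere at 4:1
#' sphere-to-background ratio. All are water-filled (mu = 0.0969 1/cm at
#' 511 keV). Grids are finer than the scanner crystal pitch: 0.5 mm in-plane
#' voxels (90x90 mouse, 140x140 rat), five 2 mm slices standing in for a
#' short axial FOV (seven slices for the hot-sphere phantom, so the sphere
#' fits axially). The hot sphere (radius 6 mm, centred 10 mm off-axis) is
#' a stated choice: the studies report only the ratio, not the sphere size.
#'
#' @param fiducials optional fiducial list, e.g. [default_fiducials()].
#' @param n_slices number of axial slices (use 1 for a purely 2D study).
#' @return A [phantom_spec()].
#' @export
mouse_phantom <- function(fiducials = NULL, n_slices = 5L) {
  phantom_spec("uniform-cylinder", diameter_mm = 30, length_mm = 45,
               activity_concentration = 1.0, material_mu = 0.0969,
               fiducials = fiducials,
               grid = list(n_x = 90L, n_y = 90L, n_slices = n_slices,
                           voxel_mm = 0.5, slice_mm = 2))
}

#' @rdname mouse_phantom
#' @export
rat_phantom <- function(fiducials = NULL, n_slices = 5L) {
  phantom_spec("uniform-cylinder", diameter_mm = 50, length_mm = 80,
               activity_concentration = 0.5, material_mu = 0.0969,
               fiducials = fiducials,
               grid = list(n_x = 140L, n_y = 140L, n_slices = n_slices,
                           voxel_mm = 0.5, slice_mm = 2))
}

#' @rdname mouse_phantom
#' @export
hot_sphere_phantom <- function(fiducials = NULL, n_slices = 7L) {
  phantom_spec("cylinder-with-hot-sphere", diameter_mm = 50, length_mm = 80,
               activity_concentration = 0.5, material_mu = 0.0969,
               sphere_center_mm = c(10, 0, 0), sphere_radius_mm = 6,
               sphere_to_background_ratio = 4,
               fiducials = fiducials,
               grid = list(n_x = 140L, n_y = 140L, n_slices = n_slices,
                           voxel_mm = 0.5, slice_mm = 2))
}

#' Default coregistration fiducials
#'
#' Three beads around a cylinder of the given diameter, at distinct activity
#' concentrations (5, 4, 3 MBq/cc) with attenuation coefficients in the same
#' rank order (0.20, 0.17, 0.14 1/cm), so that intensity rank gives the same
#' correspondence in the emission and CT images. Beads sit in the central
#' slice plane; their axial centroids are then exact by symmetry.
#'
#' @param diameter_mm diameter of the phantom the beads surround.
#' @param standoff_mm gap between cylinder surface and bead centres.
#' @param radius_mm bead radius.
#' @return A list of fiducial descriptors for [phantom_spec()].
#' @export
default_fiducials <- function(diameter_mm, standoff_mm = 5, radius_mm = 2) {
  r <- diameter_mm / 2 + standoff_mm
  ang <- c(90, 200, 330) * pi / 180
  conc <- c(5, 4, 3); mu <- c(0.20, 0.17, 0.14)
  lapply(1:3, function(i)
    list(center_mm = c(r * cos(ang[i]), r * sin(ang[i]), 0),
         radius_mm = radius_mm, concentration = conc[i], mu = mu[i]))
}

# --- rasterization ----------------------------------------------------------

# Coverage fraction of each voxel by an analytic solid, approximated by
# regular subvoxel sampling (anti-aliased boundary). `point_map`, if given,
# maps grid mm coordinates to the phantom's world frame before the membership
# test (used to generate images on a rigidly offset grid).
raster_coverage <- function(grid, member_fun, point_map = NULL,
                            ss_xy = 5L, ss_z = 3L, zvary = TRUE) {
  nx <- grid$n_x; ny <- grid$n_y; nz <- grid$n_slices
  hx <- grid$voxel_mm; hz <- grid$slice_mm
  origin <- c(-nx * hx / 2, -ny * hx / 2, -nz * hz / 2)
  off1 <- (seq_len(ss_xy) - 0.5) / ss_xy        # subvoxel offsets in (0,1)
  offz <- if (zvary) (seq_len(ss_z) - 0.5) / ss_z else 0.5
  nsz <- length(offz)
  cov <- array(0, c(nx, ny, nz))
  xs0 <- origin[1] + (seq_len(nx) - 1) * hx
  ys0 <- origin[2] + (seq_len(ny) - 1) * hx
  for (k in seq_len(nz)) {
    z0 <- origin[3] + (k - 1) * hz
    acc <- matrix(0, nx, ny)
    for (oz in offz) {
      z <- z0 + oz * hz
      for (ox in off1) for (oy in off1) {
        px <- xs0 + ox * hx; py <- ys0 + oy * hx
        P <- cbind(rep(px, times = ny), rep(py, each = nx), z)
        if (!is.null(point_map)) P <- point_map(P)
        acc <- acc + matrix(member_fun(P), nx, ny)
      }
    }
    cov[, , k] <- acc / (ss_xy * ss_xy * nsz)
  }
  cov
}

member_cylinder <- function(spec) {
  R <- spec$diameter_mm / 2; hl <- spec$length_mm / 2
  function(P) (P[, 1]^2 + P[, 2]^2 <= R^2) & (abs(P[, 3]) <= hl)
}

member_sphere <- function(center, radius) {
  function(P) (P[, 1] - center[1])^2 + (P[, 2] - center[2])^2 +
    (P[, 3] - center[3])^2 <= radius^2
}

#' Rasterize a phantom into activity and attenuation maps
#'
#' Voxelizes the analytic phantom onto its grid with area-weighted
#' (anti-aliased) boundary voxels: each boundary voxel receives the fraction
#' of its volume covered by the solid, estimated by regular subvoxel
#' sampling. The activity map equals the background concentration inside the
#' cylinder, scaled by the sphere ratio inside a hot sphere and by the bead
#' concentration inside fiducials, and is zero outside; the attenuation map
#' equals `material_mu` inside the cylinder and the bead `mu` inside
#' fiducials, zero outside. Rasterization is deterministic.
#'
#' @param spec a [phantom_spec()].
#' @param point_map optional function mapping n x 3 grid coordinates (mm) to
#'   phantom world coordinates before the membership test; used to sample the
#'   phantom on a rigidly offset grid (e.g. a CT frame).
#' @return A list with elements `activity` and `mu`, both [voxel_image()]s.
#' @examples
#' ph <- make_phantom(mouse_phantom())
#' ph$mu$values[45, 45, 3]   # water at 511 keV
#' @export
make_phantom <- function(spec, point_map = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  zvary <- g$n_slices * g$slice_mm > spec$length_mm || !is.null(spec$fiducials)
  body <- raster_coverage(g, member_cylinder(spec), point_map,
                          zvary = zvary)
  act <- spec$activity_concentration * body
  mu <- spec$material_mu * body
  if (spec$kind == "cylinder-with-hot-sphere") {
    sph <- raster_coverage(g, member_sphere(spec$sphere_center_mm,
                                            spec$sphere_radius_mm),
                           point_map, zvary = TRUE)
    act <- act + spec$activity_concentration *
      (spec$sphere_to_background_ratio - 1) * sph
  }
  for (f in spec$fiducials) {
    bead <- raster_coverage(g, member_sphere(f$center_mm, f$radius_mm),
                            point_map, zvary = TRUE)
    act <- act + f$concentration * bead
    mu <- mu + f$mu * bead
  }
  spacing <- c(g$voxel_mm, g$voxel_mm, g$slice_mm)
  list(activity = voxel_image(act, spacing, role = "activity"),
       mu = voxel_image(mu, spacing, role = "mu"))
}

#' Scale a uniform background by a hot-sphere insert
#'
#' Multiplies the activity inside a sphere so that the sphere:background mean
#' ratio equals `spec$sphere_to_background_ratio`. The background must be
#' uniform inside the body. Provided as a standalone step for building hot
#' lesions into an existing uniform phantom image.
#'
#' @param activity activity [voxel_image()] with uniform positive background.
#' @param spec a [phantom_spec()] of kind `"cylinder-with-hot-sphere"` (its
#'   sphere fields are used).
#' @return The modified activity image.
#' @export
add_hot_sphere <- function(activity, spec) {
  stopifnot(is_voxel_image(activity), inherits(spec, "phantom_spec"))
  ratio <- spec$sphere_to_background_ratio
  if (is.null(ratio) || ratio < 1)
    stop("'sphere_to_background_ratio' must be >= 1 (hot sphere only)")
  if (ratio == 1) return(activity)
  g <- spec$grid
  sph <- raster_coverage(g, member_sphere(spec$sphere_center_mm,
                                          spec$sphere_radius_mm),
                         zvary = TRUE)
  activity$values <- activity$values * (1 + (ratio - 1) * sph)
  activity
}

#' Generate a synthetic CT image from an attenuation map
#'
#' Inverts the quadratic calibration (the soft-tissue, monotonically
#' increasing branch of the parabola) to turn each attenuation value back
#' into a CT number, then optionally adds seeded Gaussian noise. Together
#' with [hu_to_mu()] this is an exact round trip at zero noise, so synthetic
#' CT volumes are always consistent with whatever calibration curve is in
#' force.
#'
#' @param mu attenuation [voxel_image()] (1/cm).
#' @param curve a [calibration_curve()].
#' @param noise_sd_hu standard deviation of additive Gaussian CT noise (HU).
#' @param seed integer seed for the noise draw.
#' @return A [voxel_image()] with role `"hu"`.
#' @export
make_synthetic_ct <- function(mu, curve, noise_sd_hu = 0, seed = 1L) {
  stopifnot(is_voxel_image(mu), mu$role == "mu")
  hu <- mu_to_hu(mu$values, curve)
  if (noise_sd_hu > 0)
    hu <- hu + withr::with_seed(as.integer(seed),
                                stats::rnorm(length(hu), sd = noise_sd_hu))
  voxel_image(array(hu, dim(mu$values)), mu$spacing, mu$origin, role = "hu")
}

#' Read a phantom specification from a key-value text configuration
#'
#' @param path YAML file with the fields of [phantom_spec()] (nested
#'   `grid:`, `fiducials:` sections).
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_phantom_spec(cfg)
}

as_phantom_spec <- function(cfg) {
  known <- c("kind", "diameter_mm", "length_mm", "activity_concentration",
             "material_mu", "sphere_center_mm", "sphere_radius_mm",
             "sphere_to_background_ratio", "fiducials", "grid")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown phantom fields: ", paste(bad, collapse = ", "))
  do.call(phantom_spec, cfg)
}
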