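#' @import Matrix
NULL

# Cache of system matrices keyed by geometry + grid, so repeated forward /
# back projections (OSEM, pipelines, tests) reuse one factorization-free
# sparse matrix per configuration.
.proj_cache <- new.env(parent = emptyenv())

proj_cache_key <- function(geom, nx, ny, spacing, origin) {
  paste(geom$n_angles, geom$n_bins, geom$bin_width_mm,
        nx, ny, signif(spacing, 12), signif(origin[1], 12),
        signif(origin[2], 12), sep = "|")
}

#' Parallel-beam system matrix
#'
#' Builds the sparse line-integral operator A mapping a 2D image (column-major
#' vector, x fastest) to a sinogram vector ordered angle-major (all bins of
#' angle 1, then angle 2, ...). Line integration uses Joseph's
#' interpolating ray-driven method: each ray steps along the image axis most
#' aligned with its direction and linearly interpolates the perpendicular
#' coordinate, with a path-length weight per step. Entries are in mm, so
#' `A %*% x` is the discrete Radon transform in value x mm. The transpose is
#' the exact adjoint, which is what OSEM requires.
#'
#' Matrices are cached per (geometry, grid) within the session.
#'
#' @param geom a [sinogram_geometry()].
#' @param nx,ny image dimensions (pixels).
#' @param spacing in-plane pixel size (mm, isotropic).
#' @param origin in-plane mm position of the corner of pixel (0, 0).
#' @return A `dgCMatrix` with `n_angles * n_bins` rows and `nx * ny` columns.
#' @export
radon_matrix <- function(geom, nx, ny, spacing,
                         origin = c(-nx * spacing / 2, -ny * spacing / 2)) {
  key <- proj_cache_key(geom, nx, ny, spacing, origin)
  hit <- .proj_cache[[key]]
  if (!is.null(hit)) return(hit)
  nb <- geom$n_bins
  s <- bin_centers(geom)
  h <- spacing
  xs <- origin[1] + (seq_len(nx) - 0.5) * h   # pixel-centre coordinates
  ys <- origin[2] + (seq_len(ny) - 0.5) * h
  ii <- jj <- vv <- vector("list", geom$n_angles)
  angs <- projection_angles(geom)
  for (a in seq_along(angs)) {
    co <- cos(angs[a]); si <- sin(angs[a])
    # ray: p(t) = s*(co, si) + t*(-si, co)
    if (abs(co) >= abs(si)) {
      # y-driven: for each image row y_j solve for x on the ray
      t <- (rep(ys, each = nb) - rep(s * si, times = ny)) / co
      x <- rep(s * co, times = ny) - t * si
      fi <- (x - origin[1]) / h - 0.5          # fractional pixel index (0-based)
      w <- h / abs(co)
      other <- rep(seq_len(ny), each = nb)     # row index j
      stride_other <- nx; stride_fi <- 1L
    } else {
      # x-driven: for each image column x_i solve for y on the ray
      t <- (rep(xs, each = nb) - rep(s * co, times = nx)) / (-si)
      y <- rep(s * si, times = nx) + t * co
      fi <- (y - origin[2]) / h - 0.5
      w <- h / abs(si)
      other <- rep(seq_len(nx), each = nb)     # column index i
      stride_other <- 1L; stride_fi <- nx
    }
    bin <- rep(seq_len(nb), times = length(fi) / nb)
    i0 <- floor(fi); fr <- fi - i0
    # two interpolation taps per step
    idx0 <- i0 + 1L; idx1 <- i0 + 2L
    n_along <- if (abs(co) >= abs(si)) nx else ny
    keep0 <- idx0 >= 1L & idx0 <= n_along
    keep1 <- idx1 >= 1L & idx1 <= n_along & fr > 0
    col0 <- (idx0 - 1L) * stride_fi + (other - 1L) * stride_other + 1L
    col1 <- (idx1 - 1L) * stride_fi + (other - 1L) * stride_other + 1L
    row <- (a - 1L) * nb + bin
    ii[[a]] <- c(row[keep0], row[keep1])
    jj[[a]] <- c(col0[keep0], col1[keep1])
    vv[[a]] <- c(((1 - fr) * w)[keep0], (fr * w)[keep1])
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(geom$n_angles * nb, nx * ny))
  .proj_cache[[key]] <- A
  A
}

check_inplane <- function(image) {
  if (abs(image$spacing[1] - image$spacing[2]) > 1e-9 * image$spacing[1])
    stop("projector requires isotropic in-plane voxel spacing")
}

check_truncation <- function(image, geom) {
  d <- dim(image$values)
  r <- sqrt(outer(voxel_centers(image, 1)^2, voxel_centers(image, 2)^2, "+"))
  outside <- r > geom$fov_mm / 2
  if (any(outside) &&
      any(abs(image$values[rep(outside, d[3])]) > 0))
    stop("truncation error: image has nonzero values outside the ",
         sprintf("%.4g mm radial field of view", geom$fov_mm))
}

sino_from_vec <- function(v, geom) t(matrix(v, geom$n_bins, geom$n_angles))
vec_from_sino <- function(m, geom) as.numeric(t(m))

#' Forward Radon transform (line integrals)
#'
#' Projects a voxel image slice by slice onto the sinogram geometry. Entry
#' `(phi, s)` is the integral of the image along the line of response at
#' angle `phi` and radial position `s`, in value x mm.
#'
#' @param image a [voxel_image()] with isotropic in-plane spacing.
#' @param geom a [sinogram_geometry()]; the object must fit inside its FOV.
#' @return A [sinogram()] of kind `"line-integral"`.
#' @export
radon_forward <- function(image, geom = sinogram_geometry()) {
  stopifnot(is_voxel_image(image))
  check_inplane(image)
  check_truncation(image, geom)
  d <- dim(image$values)
  A <- radon_matrix(geom, d[1], d[2], image$spacing[1], image$origin[1:2])
  out <- array(0, c(geom$n_angles, geom$n_bins, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- sino_from_vec(as.numeric(A %*% as.numeric(image$values[, , k])), geom)
  sinogram(out, geom, kind = "line-integral")
}

#' Backprojection (adjoint of the forward projector)
#'
#' Applies the exact transpose of the matrix used by [radon_forward()].
#' Needed by the OSEM update; exported because the adjoint pairing
#' `<Ax, y> == <x, A'y>` is a correctness contract worth checking directly.
#'
#' @param s a [sinogram()].
#' @param grid target grid: list with `n_x`, `n_y`, `voxel_mm` (and
#'   optionally `n_slices`, `slice_mm`), or a template [voxel_image()].
#' @return A [voxel_image()] (role `"activity"`).
#' @export
radon_backward <- function(s, grid) {
  stopifnot(is_sinogram(s))
  g <- as_recon_grid(grid, dim(s$values)[3])
  A <- radon_matrix(s$geometry, g$n_x, g$n_y, g$voxel_mm, g$origin[1:2])
  d3 <- dim(s$values)[3]
  out <- array(0, c(g$n_x, g$n_y, d3))
  for (k in seq_len(d3))
    out[, , k] <- matrix(as.numeric(Matrix::crossprod(A, vec_from_sino(s$values[, , k], s$geometry))),
                         g$n_x, g$n_y)
  voxel_image(out, g$spacing, g$origin, role = "activity")
}

#' Attenuation-correction-factor sinogram
#'
#' For each line of response, the probability that both annihilation photons
#' escape the object is `exp(-integral of mu dl)` over the full chord, so the
#' multiplicative correction factor is its reciprocal,
#' `ACF = exp(+integral of mu dl) >= 1`. The attenuation map is in 1/cm;
#' path lengths are computed in mm and converted by /10 exactly once, at the
#' exponent.
#'
#' @param mu attenuation [voxel_image()] (role `"mu"`, 1/cm).
#' @param geom a [sinogram_geometry()].
#' @return A [sinogram()] of kind `"acf"`.
#' @examples
#' # 50 mm water cylinder: central-LOR ACF = exp(0.0969 * 5) ~ 1.62
#' @export
acf_sinogram <- function(mu, geom = sinogram_geometry()) {
  stopifnot(is_voxel_image(mu))
  if (any(mu$values < 0)) stop("attenuation map must be nonnegative")
  li <- radon_forward(mu, geom)       # (1/cm) x mm
  sinogram(exp(li$values / 10), geom, kind = "acf")
}

#' Attenuated forward projection (attenuated Radon transform)
#'
#' Models the measured PET projections: the line integral of activity along
#' each LOR damped by the object's attenuation,
#' `p(s, phi) = integral of f exp(-integral of mu dl) dr`. Because the
#' attenuation factor in PET depends on the whole chord rather than the
#' emission point, it factors out of the activity integral, and the operation
#' equals the unattenuated projection divided elementwise by the ACF
#' sinogram; that identity is exact and is asserted by the test suite.
#'
#' @param activity activity [voxel_image()].
#' @param mu attenuation [voxel_image()] on the same grid (1/cm).
#' @param geom a [sinogram_geometry()].
#' @return A [sinogram()] of kind `"line-integral"`.
#' @export
attenuated_forward <- function(activity, mu, geom = sinogram_geometry()) {
  stopifnot(is_voxel_image(activity), is_voxel_image(mu))
  if (!identical(dim(activity$values), dim(mu$values)) ||
      max(abs(activity$spacing - mu$spacing)) > 1e-9)
    stop("shape error: activity and attenuation maps must share one grid")
  p <- radon_forward(activity, geom)
  acf <- acf_sinogram(mu, geom)
  sinogram(p$values / acf$values, geom, kind = "line-integral")
}

#' Poisson count sampling of a sinogram
#'
#' Scales a nonnegative sinogram so that its total equals
#' `total_expected_counts`, then draws independent Poisson counts per
#' element with a fixed seed. This is where activity units (MBq/cc) leave
#' the simulation: everything downstream is in counts.
#'
#' @param s a [sinogram()] with nonnegative values.
#' @param total_expected_counts expected total number of coincidences (> 0).
#' @param seed integer seed.
#' @return A [sinogram()] of kind `"counts"`.
#' @export
poisson_sample <- function(s, total_expected_counts, seed = 1L) {
  stopifnot(is_sinogram(s))
  if (any(s$values < 0)) stop("sinogram must be nonnegative")
  if (total_expected_counts <= 0) stop("'total_expected_counts' must be > 0")
  tot <- sum(s$values)
  if (tot == 0)
    return(sinogram(array(0, dim(s$values)), s$geometry, kind = "counts"))
  lam <- s$values * (total_expected_counts / tot)
  counts <- withr::with_seed(as.integer(seed),
                             stats::rpois(length(lam), lam))
  sinogram(array(as.numeric(counts), dim(s$values)), s$geometry,
           kind = "counts")
}
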