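#' Voxelized scalar image
#'
#' The basic spatial container of the package: a 3D scalar grid (2D images are
#' stored with a single slice) together with its voxel spacing and origin in
#' millimetres, and a role tag saying what the values mean. Coordinates follow
#' a single convention throughout the package: voxel indices are 0-based in
#' formulas, extents are half-open, and the centre of voxel `(i, j, k)` sits at
#' `origin + (c(i, j, k) + 0.5) * spacing` in mm. By default the origin is
#' chosen so that the grid is centred on `(0, 0, 0)`, which is also the
#' rotation axis of the projector.
#'
#' @param values numeric array (2D or 3D); 2D input is promoted to one slice.
#' @param spacing voxel spacing in mm, length 1 (isotropic) or 3.
#' @param origin position (mm) of the corner of voxel `(0, 0, 0)`; default
#'   centres the grid on the isocenter.
#' @param role one of `"activity"` (counts/s-like emission values), `"hu"`
#'   (CT numbers), `"mu"` (linear attenuation coefficients at 511 keV, 1/cm),
#'   `"mask"` (binary 0/1).
#' @return An object of class `voxel_image`.
#' @examples
#' img <- voxel_image(matrix(1, 10, 10), spacing = 0.5, role = "activity")
#' dim(img$values)
#' @export
voxel_image <- function(values, spacing = 1,
                        origin = NULL,
                        role = c("activity", "hu", "mu", "mask")) {
  role <- match.arg(role)
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 2D matrix or 3D array")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be strictly positive on every axis")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite 3-vector (mm)")
  if (role == "mu" && any(values < 0, na.rm = TRUE))
    stop("attenuation maps (role = 'mu') must be nonnegative")
  if (role == "mask" && !all(values %in% c(0, 1)))
    stop("masks must contain only 0 and 1")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), role = role),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_image> %s, %d x %d x %d voxels, spacing %s mm\n",
              x$role, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, values in [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

is_voxel_image <- function(x) inherits(x, "voxel_image")

#' Voxel-centre coordinates along one axis
#'
#' @param image a [voxel_image()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-centre positions in mm.
#' @export
voxel_centers <- function(image, axis) {
  stopifnot(is_voxel_image(image), axis %in% 1:3)
  n <- dim(image$values)[axis]
  image$origin[axis] + (seq_len(n) - 0.5) * image$spacing[axis]
}

# World coordinates (n x 3 matrix, mm) of every voxel centre, x fastest.
voxel_center_grid <- function(image) {
  d <- dim(image$values)
  xs <- voxel_centers(image, 1); ys <- voxel_centers(image, 2)
  zs <- voxel_centers(image, 3)
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Read and write voxel images as NIfTI-1
#'
#' Volumes are stored as single-file NIfTI-1 with the voxel spacing in
#' `pixdim` and the position of the first voxel centre in the qform/sform
#' offset (RAS, diagonal affine: the package does not reorient oblique
#' volumes). `write_nifti()` stores values as 32-bit float. When a file
#' carries no usable affine, the grid is assumed centred on the isocenter
#' (the package default) and a warning is emitted.
#'
#' @param image a [voxel_image()].
#' @param path file path (`.nii`).
#' @param role role tag to assign on read (the tag is not stored in the file).
#' @return `read_nifti()` returns a [voxel_image()]; `write_nifti()` returns
#'   `path` invisibly.
#' @export
write_nifti <- function(image, path) {
  stopifnot(is_voxel_image(image))
  affine <- diag(4)
  diag(affine)[1:3] <- image$spacing
  # NIfTI maps 0-based voxel indices to mm: offset = centre of voxel (0,0,0)
  affine[1:3, 4] <- image$origin + 0.5 * image$spacing
  nii <- RNifti::asNifti(image$values,
                         reference = list(pixdim = c(1, image$spacing,
                                                     0, 0, 0, 0)),
                         datatype = "float")
  RNifti::qform(nii) <- structure(affine, code = 2L)
  RNifti::sform(nii) <- structure(affine, code = 2L)
  RNifti::writeNifti(nii, path, datatype = "float")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path, role = c("activity", "hu", "mu", "mask")) {
  role <- match.arg(role)
  nii <- RNifti::readNifti(path)
  vals <- as.array(nii)
  vals <- array(as.numeric(vals), dim(vals))   # strip niftiImage attributes
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
  if (length(dim(vals)) != 3L)
    stop("unsupported NIfTI layout: expected 2D/3D volume, got dim field [",
         paste(dim(vals), collapse = ", "), "]")
  hdr <- RNifti::niftiHeader(nii)
  spacing <- abs(hdr$pixdim[2:4])
  if (any(spacing <= 0)) stop("unsupported NIfTI: nonpositive pixdim field")
  if (hdr$sform_code > 0 || hdr$qform_code > 0) {
    affine <- RNifti::xform(nii)
    origin <- affine[1:3, 4] - 0.5 * spacing
    if (max(abs(affine[1:3, 1:3] - diag(spacing))) > 1e-4 * max(spacing))
      warning("non-diagonal affine: orientation ignored, spacing/offset kept")
  } else {
    warning("NIfTI file has no affine; assuming grid centred on the isocenter")
    origin <- -dim(vals) * spacing / 2
  }
  voxel_image(vals, spacing = spacing, origin = origin, role = role)
}
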