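#' Parallel-beam sinogram geometry
#'
#' Describes the sampling of projection space: `n_angles` projection angles
#' uniform over `[0, pi)` and `n_bins` radial bins of width `bin_width_mm`
#' centred on the isocenter. `n_bins` must be odd so that the central bin's
#' line of response passes through the rotation axis. The radial field of view
#' is `n_bins * bin_width_mm`; objects must fit inside it (no truncation).
#'
#' Defaults (120 angles, 175 bins of 0.5 mm) sample a 87.5 mm transaxial FOV
#' at the Nyquist rate for 0.5 mm voxels.
#'
#' @param n_angles number of projection angles over `[0, pi)`.
#' @param n_bins odd number of radial bins.
#' @param bin_width_mm radial bin width (mm).
#' @return An object of class `sinogram_geometry`.
#' @export
sinogram_geometry <- function(n_angles = 120L, n_bins = 175L,
                              bin_width_mm = 0.5) {
  n_angles <- as.integer(n_angles); n_bins <- as.integer(n_bins)
  if (n_angles < 1L) stop("'n_angles' must be >= 1")
  if (n_bins < 1L || n_bins %% 2L == 0L)
    stop("'n_bins' must be odd so the central bin passes through isocenter")
  if (bin_width_mm <= 0) stop("'bin_width_mm' must be positive")
  structure(list(n_angles = n_angles, n_bins = n_bins,
                 bin_width_mm = bin_width_mm,
                 fov_mm = n_bins * bin_width_mm),
            class = "sinogram_geometry")
}

#' @export
print.sinogram_geometry <- function(x, ...) {
  cat(sprintf("<sinogram_geometry> %d angles over [0, pi), %d bins x %.3g mm (FOV %.4g mm)\n",
              x$n_angles, x$n_bins, x$bin_width_mm, x$fov_mm))
  invisible(x)
}

projection_angles <- function(geom) (seq_len(geom$n_angles) - 1) * pi / geom$n_angles
bin_centers <- function(geom) (seq_len(geom$n_bins) - (geom$n_bins + 1) / 2) * geom$bin_width_mm

same_geometry <- function(a, b) {
  a$n_angles == b$n_angles && a$n_bins == b$n_bins &&
    isTRUE(all.equal(a$bin_width_mm, b$bin_width_mm))
}

#' Sinogram container
#'
#' Projection data indexed `[angle, bin, slice]` with its geometry and a kind
#' tag: `"line-integral"` for values in value x mm, `"counts"` for Poisson
#' count data (nonnegative integers), `"acf"` for attenuation correction
#' factors `exp(+integral of mu dl) >= 1`.
#'
#' @param values numeric array `n_angles x n_bins [x n_slices]`.
#' @param geometry a [sinogram_geometry()].
#' @param kind data kind (see above).
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry,
                     kind = c("line-integral", "counts", "acf")) {
  kind <- match.arg(kind)
  stopifnot(inherits(geometry, "sinogram_geometry"))
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 2D or 3D array (angle x bin [x slice])")
  d <- dim(values)
  if (d[1] != geometry$n_angles || d[2] != geometry$n_bins)
    stop(sprintf("sinogram shape %d x %d does not match geometry %d x %d",
                 d[1], d[2], geometry$n_angles, geometry$n_bins))
  storage.mode(values) <- "double"
  if (kind == "acf" && any(values < 1 - 1e-9))
    stop("ACF sinograms must be >= 1 everywhere")
  if (kind == "counts" &&
      (any(values < 0) || any(abs(values - round(values)) > 1e-9)))
    stop("count sinograms must hold nonnegative integers")
  structure(list(values = values, geometry = geometry, kind = kind),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram> %s, %d angles x %d bins x %d slice(s), sum %.6g\n",
              x$kind, d[1], d[2], d[3], sum(x$values)))
  invisible(x)
}

is_sinogram <- function(x) inherits(x, "sinogram")

#' Read and write sinograms as raw float32 plus a JSON sidecar
#'
#' The array is stored little-endian 32-bit float in `[angle, bin, slice]`
#' order (angle fastest); the sidecar `<path>.json` carries the geometry,
#' kind, shape and angle convention so the round trip is lossless up to
#' float32 precision.
#'
#' @param s a [sinogram()].
#' @param path path of the raw array file (sidecar written as `<path>.json`).
#' @return `read_sinogram()` returns a [sinogram()]; `write_sinogram()`
#'   returns `path` invisibly.
#' @export
write_sinogram <- function(s, path) {
  stopifnot(is_sinogram(s))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(s$values), con, size = 4L, endian = "little")
  meta <- list(n_angles = s$geometry$n_angles, n_bins = s$geometry$n_bins,
               bin_width_mm = s$geometry$bin_width_mm,
               n_slices = dim(s$values)[3], angle_range = "[0,pi)",
               kind = s$kind, dtype = "float32le")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- sinogram_geometry(meta$n_angles, meta$n_bins, meta$bin_width_mm)
  n <- meta$n_angles * meta$n_bins * meta$n_slices
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "numeric", n = n + 1L, size = 4L, endian = "little")
  if (length(vals) != n)
    stop(sprintf("sinogram array holds %d values but sidecar promises %d",
                 length(vals), n))
  sinogram(array(vals, c(meta$n_angles, meta$n_bins, meta$n_slices)),
           geom, kind = meta$kind)
}
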