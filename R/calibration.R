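#' Reference 511 keV attenuation coefficients of calibration materials
#'
#' The NIST-tabulated densities and linear attenuation coefficients at
#' 511 keV of the insert materials of a mini CT quality-control phantom
#' (air, polyethylene, polystyrene, water, acrylic, PTFE, aluminum), shipped
#' as plain text with the package. Water is 0.0969 1/cm; acrylic 0.1120;
#' Teflon 0.1886; aluminum 0.2280.
#'
#' @return A data frame with columns `material`, `density`, `mu_511`.
#' @export
nist_materials <- function() {
  utils::read.csv(system.file("extdata", "nist_materials_511kev.csv",
                              package = "petac"),
                  stringsAsFactors = FALSE)
}

#' Quadratic HU-to-mu calibration curve
#'
#' `mu = a1 * HU^2 + a2 * HU + a3` maps scanner CT numbers to linear
#' attenuation coefficients at 511 keV (1/cm). The curve is only trusted over
#' `hu_domain`; outside it, evaluation is flat (clamped to the nearest domain
#' edge) because a downward-opening quadratic would map very dense material
#' to falling mu. The curve must be non-decreasing over its domain.
#'
#' @param a1,a2,a3 quadratic coefficients (1/cm per HU^2, per HU, and 1/cm).
#' @param r_squared coefficient of determination of the fit (reported only).
#' @param hu_domain length-2 numeric, the HU range over which the curve is
#'   trusted.
#' @return An object of class `calibration_curve`.
#' @seealso [fit_calibration()], [default_calibration()]
#' @export
calibration_curve <- function(a1, a2, a3, r_squared = NA_real_,
                              hu_domain = c(-1100, 2000)) {
  stopifnot(length(hu_domain) == 2L, hu_domain[1] < hu_domain[2])
  # derivative 2*a1*HU + a2 is linear: checking the endpoints suffices
  dends <- 2 * a1 * hu_domain + a2
  if (any(dends < -1e-12))
    stop("calibration curve must be non-decreasing over its HU domain ",
         sprintf("(derivative is %.3g at HU = %.5g)",
                 min(dends), hu_domain[which.min(dends)]))
  structure(list(a1 = a1, a2 = a2, a3 = a3, r_squared = r_squared,
                 hu_domain = as.numeric(hu_domain)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> mu = %.6g HU^2 + %.6g HU + %.6g (1/cm)\n",
              x$a1, x$a2, x$a3))
  cat(sprintf("  r^2 = %.4g, HU domain [%.5g, %.5g]\n",
              x$r_squared, x$hu_domain[1], x$hu_domain[2]))
  invisible(x)
}

#' Published calibration of an 80 kVp small-animal CT scanner
#'
#' The quadratic calibration measured on the CT system the package models:
#' `a1 = -2.05e-8`, `a2 = 9.66e-5`, `a3 = 0.12` (1/cm), with r^2 = 0.993
#' over the insert range. Note that on this scanner's CT-number scale
#' `mu(0) = 0.12`, not the water value, i.e. the scale is not anchored at
#' water = 0 HU; the package therefore always generates synthetic CT volumes
#' by inverting the active curve rather than assuming a standard Hounsfield
#' anchor.
#'
#' @return A [calibration_curve()].
#' @export
default_calibration <- function() {
  calibration_curve(a1 = -2.05e-8, a2 = 9.66e-5, a3 = 0.12,
                    r_squared = 0.993, hu_domain = c(-1100, 2000))
}

#' Fit the quadratic HU-to-mu calibration
#'
#' Ordinary (unweighted) least squares of the 511 keV attenuation
#' coefficients on the measured CT numbers of the phantom inserts.
#'
#' @param points data frame with columns `measured_hu` and `mu_511` (and
#'   optionally `material`, `density`), e.g. from
#'   [read_calibration_points()].
#' @param margin_fraction the fitted HU domain is the data range widened by
#'   this fraction of the range on each side.
#' @return A [calibration_curve()].
#' @export
fit_calibration <- function(points, margin_fraction = 0.05) {
  stopifnot(is.data.frame(points),
            all(c("measured_hu", "mu_511") %in% names(points)))
  if (!is.null(points$material) && anyDuplicated(points$material))
    stop("fit error: calibration materials must be unique")
  if (any(points$mu_511 < 0)) stop("fit error: mu_511 must be >= 0")
  hu <- points$measured_hu; mu <- points$mu_511
  if (length(unique(hu)) < 3L)
    stop("fit error: need at least 3 distinct HU values for a quadratic fit")
  fit <- stats::lm(mu ~ hu + I(hu^2))
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((mu - mean(mu))^2)
  r2 <- 1 - ss_res / ss_tot
  margin <- margin_fraction * diff(range(hu))
  calibration_curve(a1 = unname(co[3]), a2 = unname(co[2]),
                    a3 = unname(co[1]), r_squared = r2,
                    hu_domain = c(min(hu) - margin, max(hu) + margin))
}

#' Read calibration points from delimited text
#'
#' @param path delimited text file (comma or whitespace separated) with
#'   columns `material`, `density`, `mu_511`, `measured_hu`.
#' @return A data frame of calibration points.
#' @export
read_calibration_points <- function(path) {
  first <- readLines(path, n = 1L)
  pts <- if (grepl(",", first)) utils::read.csv(path, stringsAsFactors = FALSE)
         else utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("material", "density", "mu_511", "measured_hu")
  miss <- setdiff(need, names(pts))
  if (length(miss)) stop("calibration file lacks columns: ",
                         paste(miss, collapse = ", "))
  pts
}

eval_curve <- function(curve, hu) {
  hu <- pmin(pmax(hu, curve$hu_domain[1]), curve$hu_domain[2])
  pmax(curve$a1 * hu^2 + curve$a2 * hu + curve$a3, 0)
}

#' Convert a CT volume to a 511 keV attenuation map
#'
#' Applies the quadratic calibration voxelwise, clamps negative results to
#' zero, and evaluates CT numbers outside the curve's trusted domain at the
#' nearest domain edge (flat extrapolation). The result is a total function:
#' no input produces an error or a negative coefficient.
#'
#' @param ct CT [voxel_image()] (role `"hu"`).
#' @param curve a [calibration_curve()].
#' @return A [voxel_image()] with role `"mu"` (1/cm).
#' @export
hu_to_mu <- function(ct, curve) {
  stopifnot(is_voxel_image(ct), inherits(curve, "calibration_curve"))
  if (any(!is.finite(ct$values))) stop("CT values must be finite")
  voxel_image(array(eval_curve(curve, ct$values), dim(ct$values)),
              ct$spacing, ct$origin, role = "mu")
}

# Invert the calibration on its monotone (soft-tissue) branch:
# root of a1*HU^2 + a2*HU + (a3 - mu) = 0 continuous with HU = 0 at mu = a3.
mu_to_hu <- function(mu, curve) {
  lo <- curve$hu_domain[1]; hi <- curve$hu_domain[2]
  attain <- sort(c(eval_curve(curve, lo), eval_curve(curve, hi)))
  if (any(mu < attain[1] - 1e-12) || any(mu > attain[2] + 1e-12))
    stop(sprintf(
      "domain error: mu outside [%.4g, %.4g] 1/cm attainable by the curve over HU [%.5g, %.5g]",
      attain[1], attain[2], lo, hi))
  if (abs(curve$a1) < 1e-300) return((mu - curve$a3) / curve$a2)
  disc <- curve$a2^2 - 4 * curve$a1 * (curve$a3 - mu)
  disc <- pmax(disc, 0)
  hu <- (-curve$a2 + sqrt(disc)) / (2 * curve$a1)
  # mu values below the clamped-to-zero region invert to the domain edge
  pmin(pmax(hu, lo), hi)
}

#' Mean CT number inside a circular insert ROI
#'
#' @param ct CT [voxel_image()].
#' @param roi_center_mm in-plane ROI centre (length 2, mm).
#' @param roi_radius_mm ROI radius (mm).
#' @param slices slice indices to include (default: all).
#' @return Mean HU of the voxels whose centres fall inside the ROI.
#' @export
measure_insert_hu <- function(ct, roi_center_mm, roi_radius_mm,
                              slices = NULL) {
  stopifnot(is_voxel_image(ct))
  d <- dim(ct$values)
  if (is.null(slices)) slices <- seq_len(d[3])
  xs <- voxel_centers(ct, 1); ys <- voxel_centers(ct, 2)
  ext_x <- range(xs) + c(-0.5, 0.5) * ct$spacing[1]
  ext_y <- range(ys) + c(-0.5, 0.5) * ct$spacing[2]
  if (roi_center_mm[1] - roi_radius_mm < ext_x[1] ||
      roi_center_mm[1] + roi_radius_mm > ext_x[2] ||
      roi_center_mm[2] - roi_radius_mm < ext_y[1] ||
      roi_center_mm[2] + roi_radius_mm > ext_y[2])
    stop("ROI crosses the image edge")
  inside <- outer(xs - roi_center_mm[1], ys - roi_center_mm[2],
                  function(a, b) a^2 + b^2) <= roi_radius_mm^2
  if (!any(inside)) stop("empty ROI: no voxel centre falls inside it")
  mean(ct$values[, , slices, drop = FALSE][rep(inside, length(slices))])
}
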