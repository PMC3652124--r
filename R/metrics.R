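#' Recovery values of attenuation-corrected images
#'
#' The fractional count increase of each corrected image over the
#' uncorrected one, normalized by the CT-corrected ROI mean for *both*
#' methods:
#' `RV_CT = (ROI_AC-CT - ROI_NC) / ROI_AC-CT` and
#' `RV_SE = (ROI_AC-SE - ROI_NC) / ROI_AC-CT`.
#' The shared CT denominator makes the two recovery values directly
#' comparable; it is implemented exactly in that form.
#'
#' @param roi_nc ROI mean on the uncorrected image.
#' @param roi_ac_ct ROI mean on the CT-corrected image (> 0).
#' @param roi_ac_se ROI mean on the segmentation-corrected image (optional).
#' @return List with `rv_ct` and `rv_se`, in percent (`rv_se` is `NA` when
#'   `roi_ac_se` is missing).
#' @examples
#' recovery_values(210.34, 405.32, 396.17)  # rat phantom: 48.1 / 45.8
#' @export
recovery_values <- function(roi_nc, roi_ac_ct, roi_ac_se = NA_real_) {
  if (!is.finite(roi_ac_ct) || roi_ac_ct <= 0)
    stop("'roi_ac_ct' (the denominator) must be positive")
  list(rv_ct = 100 * (roi_ac_ct - roi_nc) / roi_ac_ct,
       rv_se = 100 * (roi_ac_se - roi_nc) / roi_ac_ct)
}

#' Flatness of a count profile
#'
#' `(Cmax - Cmin) / Cmin` in percent over the interior of a uniform object's
#' profile: it quantifies the residual cupping artifact (large before
#' attenuation correction, near zero after). With `interior_fraction < 1`
#' the profile is first restricted to the central fraction of the object's
#' support (samples above `support_threshold` of the profile maximum), which
#' excludes the partial-volume roll-off at the object edge; an edge-inclusive
#' minimum would otherwise dominate the statistic.
#'
#' @param profile numeric vector of counts, or the data frame returned by
#'   [line_profile()].
#' @param interior_fraction fraction of the object's support to keep,
#'   centred (default 1: use the samples as given).
#' @param support_threshold fraction of the profile maximum defining the
#'   object's support.
#' @return Flatness in percent.
#' @examples
#' flatness(c(100, 80, 100))  # 25
#' @export
flatness <- function(profile, interior_fraction = 1,
                     support_threshold = 0.1) {
  v <- if (is.data.frame(profile)) profile$value else as.numeric(profile)
  stopifnot(length(v) >= 2L, interior_fraction > 0, interior_fraction <= 1)
  if (interior_fraction < 1) {
    sup <- which(v > support_threshold * max(v))
    if (!length(sup)) stop("profile has no support above threshold")
    lo <- min(sup); hi <- max(sup)
    c0 <- (lo + hi) / 2; half <- (hi - lo) / 2 * interior_fraction
    v <- v[seq_along(v) >= c0 - half & seq_along(v) <= c0 + half]
  }
  cmin <- min(v); cmax <- max(v)
  if (cmin <= 0) stop("undefined flatness: Cmin <= 0 on the interior window")
  100 * (cmax - cmin) / cmin
}

#' Central line profile through an image slice
#'
#' Samples one row or column of a transaxial slice, with mm positions
#' attached, as drawn across reconstructed phantom images.
#'
#' @param image a [voxel_image()].
#' @param slice_index slice to sample (default: central slice).
#' @param axis `"x"` (profile runs along x, at fixed y) or `"y"`.
#' @param offset_mm perpendicular offset of the line from the image centre
#'   row/column (mm).
#' @return Data frame with columns `position_mm` and `value`.
#' @export
line_profile <- function(image, slice_index = NULL, axis = c("x", "y"),
                         offset_mm = 0) {
  stopifnot(is_voxel_image(image))
  axis <- match.arg(axis)
  d <- dim(image$values)
  if (is.null(slice_index)) slice_index <- (d[3] + 1L) %/% 2L
  if (slice_index < 1L || slice_index > d[3]) stop("slice index out of bounds")
  perp <- if (axis == "x") 2L else 1L
  cen <- voxel_centers(image, perp)
  j <- which.min(abs(cen - offset_mm))
  if (abs(cen[j] - offset_mm) > sum(image$spacing[perp]) / 2 + 1e-9)
    stop("offset outside the image")
  if (axis == "x")
    data.frame(position_mm = voxel_centers(image, 1),
               value = image$values[, j, slice_index])
  else
    data.frame(position_mm = voxel_centers(image, 2),
               value = image$values[j, , slice_index])
}

#' Mean value in a circular or spherical region of interest
#'
#' Voxels whose centres fall inside the region are averaged. A
#' `"cylinder"` ROI is a disk applied to the chosen slices (default: the
#' central slice, as for a ROI drawn at the centre of one transaxial
#' slice); a `"sphere"` ROI is a 3D ball.
#'
#' @param image a [voxel_image()].
#' @param center_mm ROI centre (length 2 or 3, mm).
#' @param radius_mm ROI radius (mm).
#' @param shape `"cylinder"` or `"sphere"`.
#' @param slices slice indices for cylinder ROIs (default: central slice).
#' @return Mean of the voxels in the ROI.
#' @export
roi_mean <- function(image, center_mm, radius_mm,
                     shape = c("cylinder", "sphere"), slices = NULL) {
  stopifnot(is_voxel_image(image), radius_mm > 0)
  shape <- match.arg(shape)
  d <- dim(image$values)
  xs <- voxel_centers(image, 1); ys <- voxel_centers(image, 2)
  in2d <- outer(xs - center_mm[1], ys - center_mm[2],
                function(a, b) a^2 + b^2)
  if (shape == "cylinder") {
    if (is.null(slices)) slices <- (d[3] + 1L) %/% 2L
    sel <- in2d <= radius_mm^2
    if (!any(sel)) stop("empty ROI")
    vals <- image$values[, , slices, drop = FALSE]
    return(mean(vals[rep(sel, length(slices))]))
  }
  if (length(center_mm) < 3L) stop("sphere ROI needs a 3D centre")
  zs <- voxel_centers(image, 3)
  tot <- 0; nv <- 0L
  for (k in seq_len(d[3])) {
    dz2 <- (zs[k] - center_mm[3])^2
    sel <- in2d + dz2 <= radius_mm^2
    if (any(sel)) { tot <- tot + sum(image$values[, , k][sel]); nv <- nv + sum(sel) }
  }
  if (nv == 0L) stop("empty ROI")
  tot / nv
}

#' Evaluation report of an attenuation-correction experiment
#'
#' Bundles the ROI means of the uncorrected and corrected reconstructions,
#' the recovery values, the interior-profile flatness of each image, the
#' central line profiles, and the full provenance (every parameter used).
#'
#' @param roi_nc,roi_ac_ct,roi_ac_se ROI means (cps-like units).
#' @param flatness_nc,flatness_ct,flatness_se interior flatness (percent).
#' @param profiles named list of [line_profile()] data frames.
#' @param provenance named list of configuration used.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(roi_nc, roi_ac_ct = NA_real_, roi_ac_se = NA_real_,
                        flatness_nc = NA_real_, flatness_ct = NA_real_,
                        flatness_se = NA_real_, profiles = list(),
                        provenance = list()) {
  rv <- if (is.finite(roi_ac_ct) && roi_ac_ct > 0)
    recovery_values(roi_nc, roi_ac_ct, roi_ac_se)
  else list(rv_ct = NA_real_,
            rv_se = if (is.finite(roi_ac_se) && roi_ac_se > 0)
              100 * (roi_ac_se - roi_nc) / roi_ac_se else NA_real_)
  structure(list(roi_nc = roi_nc, roi_ac_ct = roi_ac_ct,
                 roi_ac_se = roi_ac_se,
                 rv_ct = rv$rv_ct, rv_se = rv$rv_se,
                 flatness_nc = flatness_nc, flatness_ct = flatness_ct,
                 flatness_se = flatness_se,
                 profiles = profiles, provenance = provenance),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  ROI means (cps-like): NC %.4g, AC-CT %.4g, AC-SE %.4g\n",
              x$roi_nc, x$roi_ac_ct, x$roi_ac_se))
  cat(sprintf("  recovery values: RV_CT %.1f%%, RV_SE %.1f%%\n",
              x$rv_ct, x$rv_se))
  cat(sprintf("  flatness: NC %.1f%%, AC-CT %.1f%%, AC-SE %.1f%%\n",
              x$flatness_nc, x$flatness_ct, x$flatness_se))
  invisible(x)
}

#' Write an evaluation report as JSON and a delimited table
#'
#' @param report an [eval_report()].
#' @param path_json JSON output path (scalar fields plus provenance).
#' @param path_table optional tab-separated table of the ROI/RV/flatness
#'   columns.
#' @return `path_json`, invisibly.
#' @export
write_eval_report <- function(report, path_json, path_table = NULL) {
  stopifnot(inherits(report, "eval_report"))
  out <- report[c("roi_nc", "roi_ac_ct", "roi_ac_se", "rv_ct", "rv_se",
                  "flatness_nc", "flatness_ct", "flatness_se")]
  prov <- report$provenance
  prov$images <- NULL   # image payloads stay out of the JSON report
  if (!is.null(prov$phantom)) prov$phantom$fiducials <- NULL
  out$provenance <- prov
  jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(path_table)) {
    tab <- data.frame(
      image = c("original", "ct_ac", "se_ac"),
      roi_counts = c(report$roi_nc, report$roi_ac_ct, report$roi_ac_se),
      rv_percent = c(NA, report$rv_ct, report$rv_se),
      flatness_percent = c(report$flatness_nc, report$flatness_ct,
                           report$flatness_se))
    utils::write.table(tab, path_table, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path_json)
}

#' Recovery-value arithmetic of the published studies
#'
#' The ROI means reported in the published phantom and animal experiments
#' this package models, shipped as plain text. Useful as a regression
#' surface for [recovery_values()]: applying the recovery-value formulas to
#' the `roi_*` columns must reproduce the printed `rv_*_printed` columns at
#' 0.1 percentage-point precision.
#'
#' @return A data frame with the study, subject, region, the three ROI
#'   means, and the printed recovery values.
#' @export
reported_study_means <- function() {
  utils::read.csv(system.file("extdata", "published_roi_means.csv",
                              package = "petac"),
                  stringsAsFactors = FALSE)
}
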