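#' Threshold policy for emission-image segmentation
#'
#' The transmissionless route builds its attenuation map by thresholding the
#' uncorrected emission reconstruction into air versus soft tissue. The
#' default policy sets the global threshold at a fraction (10%) of the 99th
#' percentile intensity; anchoring on a high percentile instead of the
#' maximum keeps hot spots (tumour, bladder, fiducial beads) from dragging
#' the threshold up. An Otsu policy (exhaustive maximization of
#' between-class variance over observed intensities) is available as an
#' alternative. Relative policies make the mask invariant to global
#' intensity scaling.
#'
#' @param method `"relative"` or `"otsu"`.
#' @param fraction threshold as a fraction of the reference intensity
#'   (relative policy).
#' @param percentile reference percentile of the intensity distribution
#'   (relative policy).
#' @return An object of class `segment_policy`.
#' @export
segment_policy <- function(method = c("relative", "otsu"),
                           fraction = 0.1, percentile = 0.99) {
  method <- match.arg(method)
  stopifnot(fraction > 0, fraction < 1, percentile > 0, percentile <= 1)
  structure(list(method = method, fraction = fraction,
                 percentile = percentile), class = "segment_policy")
}

# Exact Otsu threshold: maximize between-class variance over candidate cuts
# at the observed sorted intensities.
otsu_threshold <- function(x) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  w1 <- k / n
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bc <- w1 * (1 - w1) * (m1 - m2)^2
  best <- which.max(bc)
  (x[best] + x[best + 1]) / 2
}

#' Segment an emission image into a body mask
#'
#' Applies a global threshold, keeps the largest connected component (the
#' body), and fills internal holes slice by slice, so cold interior
#' structures (a ventricle, a low-uptake organ) stay inside the body
#' contour. Hole filling is deliberately 2D: the reconstruction pipeline is
#' per-slice, and axially open structures should not be sealed across
#' slices.
#'
#' @param pet emission [voxel_image()], nonnegative and not identically
#'   zero.
#' @param policy a [segment_policy()].
#' @return A binary [voxel_image()] (role `"mask"`) with attribute
#'   `threshold`.
#' @export
segment_emission <- function(pet, policy = segment_policy()) {
  stopifnot(is_voxel_image(pet), inherits(policy, "segment_policy"))
  v <- pet$values
  if (any(v < 0)) stop("emission image must be nonnegative")
  if (max(v) == 0) stop("segmentation error: emission image is identically zero")
  thr <- switch(policy$method,
    relative = policy$fraction *
      stats::quantile(v, policy$percentile, names = FALSE),
    otsu = otsu_threshold(as.numeric(v)))
  mask <- v >= thr
  if (!any(mask))
    stop(sprintf("threshold error: empty mask at threshold %.4g (image max %.4g)",
                 thr, max(v)))
  labs <- label_components(mask)
  sizes <- tabulate(labs[labs > 0L], max(labs))
  body <- array(labs == which.max(sizes), dim(mask))
  filled <- body
  for (k in seq_len(dim(body)[3]))
    filled[, , k] <- EBImage::fillHull(body[, , k] * 1L) > 0
  out <- voxel_image(array(as.numeric(filled), dim(mask)), pet$spacing,
                     pet$origin, role = "mask")
  attr(out, "threshold") <- thr
  out
}

#' Uniform attenuation map from a body mask
#'
#' Assigns a single soft-tissue attenuation coefficient (default: water at
#' 511 keV, 0.0969 1/cm) inside the mask and zero outside. Bone is
#' deliberately mapped to soft tissue: the transmissionless method has no
#' tissue classes, which is its known failure mode for bone-seeking tracers.
#'
#' @param mask binary [voxel_image()] (role `"mask"`).
#' @param mu_soft soft-tissue attenuation coefficient (1/cm).
#' @return A [voxel_image()] with role `"mu"`.
#' @export
mask_to_mumap <- function(mask, mu_soft = 0.0969) {
  stopifnot(is_voxel_image(mask))
  if (mask$role != "mask") stop("'mask' must have role 'mask'")
  if (mu_soft < 0) stop("'mu_soft' must be >= 0")
  voxel_image(mask$values * mu_soft, mask$spacing, mask$origin, role = "mu")
}
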