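#' Rigid-body transform
#'
#' A proper rotation plus translation acting on mm coordinates,
#' `x_fixed = R %*% x_moving + t`. Stored (and persisted in run manifests)
#' as a 4x4 homogeneous matrix acting on column vectors of mm coordinates;
#' image origins sit at the corner of voxel (0,0,0) with voxel centres at
#' `(i + 0.5) * spacing`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation_mm length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation_mm) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1); reflections are not rigid")
  structure(list(rotation = rotation,
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%s) mm\n",
              ang, paste(signif(x$translation_mm, 4), collapse = ", ")))
  invisible(x)
}

#' In-plane rotation helper
#' @param degrees rotation angle about the z axis (degrees).
#' @param translation_mm translation (mm).
#' @return A [rigid_transform()].
#' @export
inplane_transform <- function(degrees = 0, translation_mm = c(0, 0, 0)) {
  th <- degrees * pi / 180
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rigid_transform(R, translation_mm)
}

#' Apply, compose and invert rigid transforms
#'
#' @param t,a,b [rigid_transform()] objects.
#' @param points n x 3 matrix of mm coordinates.
#' @return `transform_points()` an n x 3 matrix; `compose_transform()` the
#'   transform applying `b` then `a`; `invert_transform()` the inverse.
#' @export
transform_points <- function(t, points) {
  points <- rbind(points)  # accept a bare 3-vector
  sweep(points %*% t(t$rotation), 2, t$translation_mm, "+")
}

#' @rdname transform_points
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation_mm) + a$translation_mm)
}

#' @rdname transform_points
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation_mm))
}

#' @rdname transform_points
#' @export
as_homogeneous <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation_mm
  m
}

# --- connected components ---------------------------------------------------

# 3D 6-connected labelling: 2D labels per slice (EBImage) merged across
# adjacent slices with union-find on voxel overlap.
label_components <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    lk <- EBImage::bwlabel(mask[, , k])
    nk <- max(lk)
    lk[lk > 0] <- lk[lk > 0] + offset
    labs[, , k] <- lk
    offset <- offset + nk
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <<- rj }
  if (d[3] > 1L) for (k in seq_len(d[3] - 1L)) {
    a <- labs[, , k]; b <- labs[, , k + 1L]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) union(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  relab <- match(roots, unique(roots))
  labs[labs > 0L] <- relab[labs[labs > 0L]]
  labs
}

#' Detect fiducial markers as bright blobs
#'
#' Thresholds the image at `min + fraction * (max - min)`, labels connected
#' components, and returns the intensity-weighted centroid (mm) of each
#' component, ordered by decreasing mean intensity. A component is treated as
#' the body (and excluded) when it is the largest and at least `body_ratio`
#' times the size of the runner-up; a bead is orders of magnitude smaller
#' than a body, and this guard keeps the exclusion from eating a bead when
#' the threshold already removed the body. Weights are the intensity above
#' threshold, so the centroid is meaningful for CT images with negative
#' backgrounds too.
#'
#' @param image a [voxel_image()] (emission reconstruction or CT).
#' @param intensity_threshold_fraction threshold position within the image's
#'   intensity range (0..1).
#' @param min_voxels components smaller than this are discarded as noise.
#' @param body_ratio size ratio above which the largest component is
#'   considered the body.
#' @return An n x 3 matrix of centroids (mm), ordered by decreasing mean
#'   intensity, with attributes `sizes` and `mean_intensity`; zero rows when
#'   nothing is found.
#' @export
detect_fiducials <- function(image, intensity_threshold_fraction = 0.1,
                             min_voxels = 3L, body_ratio = 4) {
  stopifnot(is_voxel_image(image))
  v <- image$values
  rng <- range(v)
  if (rng[1] == rng[2])
    return(structure(matrix(numeric(0), 0, 3), sizes = integer(0),
                     mean_intensity = numeric(0)))
  thr <- rng[1] + intensity_threshold_fraction * diff(rng)
  labs <- label_components(v >= thr)
  n <- max(labs)
  if (n == 0L)
    return(structure(matrix(numeric(0), 0, 3), sizes = integer(0),
                     mean_intensity = numeric(0)))
  sizes <- tabulate(labs[labs > 0L], n)
  keep <- which(sizes >= min_voxels)
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  if (length(ord) >= 2L && sizes[ord[1]] >= body_ratio * sizes[ord[2]])
    ord <- ord[-1]
  if (!length(ord))
    return(structure(matrix(numeric(0), 0, 3), sizes = integer(0),
                     mean_intensity = numeric(0)))
  P <- voxel_center_grid(image)
  cent <- matrix(NA_real_, length(ord), 3)
  meanI <- numeric(length(ord))
  for (i in seq_along(ord)) {
    sel <- which(labs == ord[i])
    w <- v[sel] - thr
    if (sum(w) <= 0) w <- rep(1, length(sel))
    cent[i, ] <- colSums(P[sel, , drop = FALSE] * w) / sum(w)
    meanI[i] <- mean(v[sel])
  }
  o <- order(meanI, decreasing = TRUE)
  structure(cent[o, , drop = FALSE], sizes = sizes[ord][o],
            mean_intensity = meanI[o])
}

#' Least-squares rigid alignment of paired points
#'
#' Orthogonal Procrustes (Kabsch) with reflections excluded: finds the
#' proper rotation and translation minimizing the RMS distance between
#' `R %*% moving + t` and `fixed`. Exact (zero residual) on noise-free
#' correspondences; a reflected configuration cannot be fit by a proper
#' rotation and shows up as a large reported residual.
#'
#' @param moving,fixed n x 3 matrices of paired points (mm), n >= 3,
#'   non-collinear.
#' @return A [rigid_transform()] with attribute `rms_residual_mm`.
#' @export
estimate_rigid <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed) || nrow(moving) < 3L)
    stop("need at least 3 paired points")
  mc <- colMeans(moving); fc <- colMeans(fixed)
  M <- sweep(moving, 2, mc); F <- sweep(fixed, 2, fc)
  if (qr(M)$rank < 2L)
    stop("degenerate configuration: points are collinear")
  H <- t(M) %*% F
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- fc - as.numeric(R %*% mc)
  out <- rigid_transform(R, tr)
  res <- transform_points(out, moving) - fixed
  attr(out, "rms_residual_mm") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Resample an image through a rigid transform
#'
#' Evaluates the moving image at `R^-1 (x - t)` for every target voxel
#' centre `x`, with trilinear interpolation (positivity preserving, suitable
#' for attenuation maps) and fill value 0 (air) outside the moving image's
#' support. Single-slice volumes are interpolated in-plane only.
#'
#' @param image moving [voxel_image()].
#' @param t [rigid_transform()] mapping moving mm coordinates into the
#'   target (fixed) space.
#' @param target_grid template [voxel_image()] or [recon_grid()] defining
#'   the output grid.
#' @return A [voxel_image()] on the target grid with the moving image's
#'   role.
#' @export
resample <- function(image, t, target_grid) {
  stopifnot(is_voxel_image(image), inherits(t, "rigid_transform"))
  n3 <- if (is_voxel_image(target_grid)) dim(target_grid$values)[3]
        else dim(image$values)[3]
  g <- as_recon_grid(target_grid, n3)
  tpl <- voxel_image(array(0, c(g$n_x, g$n_y, n3)), g$spacing, g$origin,
                     role = "mask")
  X <- voxel_center_grid(tpl)
  ti <- invert_transform(t)
  Pm <- transform_points(ti, X)
  vals <- trilinear_sample(image, Pm)
  out <- array(vals, c(g$n_x, g$n_y, n3))
  if (image$role == "mu") out <- pmax(out, 0)
  voxel_image(array(out, c(g$n_x, g$n_y, n3)), g$spacing, g$origin,
              role = if (image$role == "mask") "activity" else image$role)
}

trilinear_sample <- function(image, P) {
  d <- dim(image$values)
  f <- sweep(sweep(P, 2, image$origin), 2, image$spacing, "/") - 0.5
  out <- numeric(nrow(P))
  i0 <- floor(f[, 1]); j0 <- floor(f[, 2]); k0 <- floor(f[, 3])
  fx <- f[, 1] - i0; fy <- f[, 2] - j0; fz <- f[, 3] - k0
  if (d[3] == 1L) { k0 <- rep(0, nrow(P)); fz <- rep(0, nrow(P)) }
  ok <- i0 >= -1 & i0 <= d[1] - 1 & j0 >= -1 & j0 <= d[2] - 1 &
    k0 >= -1 & k0 <= d[3] - 1
  if (!any(ok)) return(out)
  gather <- function(ii, jj, kk) {
    v <- numeric(sum(ok))
    ins <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    v[ins] <- image$values[cbind(ii[ins], jj[ins], kk[ins])]
    v
  }
  i0k <- i0[ok] + 1L; j0k <- j0[ok] + 1L; k0k <- k0[ok] + 1L
  fxk <- fx[ok]; fyk <- fy[ok]; fzk <- fz[ok]
  acc <- numeric(sum(ok))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fxk else 1 - fxk) * (if (dy) fyk else 1 - fyk) *
         (if (dz) fzk else 1 - fzk)
    nz <- w > 0
    if (any(nz)) {
      vv <- numeric(sum(ok))
      vv[nz] <- gather((i0k + dx)[nz], (j0k + dy)[nz], (k0k + dz)[nz])
      acc <- acc + w * vv
    }
  }
  out[ok] <- acc
  out
}
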