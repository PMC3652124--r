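#' Reconstruction configuration
#'
#' Parameters of the 2D ordered-subsets EM reconstruction. The scanner-side
#' studies this package models do not state their reconstruction settings;
#' the defaults (8 interleaved angular subsets, 10 iterations, uniform unit
#' initial image) give stable convergence at the package's grid sizes and
#' are recorded in every evaluation report for provenance. With
#' `n_subsets = 1` the algorithm is exactly MLEM.
#'
#' @param n_subsets number of angular subsets; must divide `n_angles`.
#' @param n_iterations full passes over all subsets.
#' @param init_value positive uniform initial image value.
#' @param ac_mode attenuation handling: `"none"`, `"precorrected"` (data were
#'   multiplied by the ACF before reconstruction; the system model is the
#'   plain Radon transform), or `"system-matrix"` (the forward model itself
#'   is damped by 1/ACF; requires the `acf` argument of
#'   [osem_reconstruct()]).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_subsets = 8L, n_iterations = 10L, init_value = 1,
                         ac_mode = c("precorrected", "none", "system-matrix")) {
  ac_mode <- match.arg(ac_mode)
  n_subsets <- as.integer(n_subsets); n_iterations <- as.integer(n_iterations)
  stopifnot(n_subsets >= 1L, n_iterations >= 1L)
  if (init_value <= 0) stop("'init_value' must be > 0")
  structure(list(n_subsets = n_subsets, n_iterations = n_iterations,
                 init_value = init_value, ac_mode = ac_mode),
            class = "recon_config")
}

#' Target grid for reconstruction
#'
#' @param n_x,n_y image dimensions (pixels).
#' @param voxel_mm in-plane pixel size (mm).
#' @param slice_mm axial spacing (mm).
#' @param origin mm position of the corner of voxel (0,0,0); default centred.
#' @return A list usable as the `grid` argument of [osem_reconstruct()] and
#'   [radon_backward()].
#' @export
recon_grid <- function(n_x, n_y, voxel_mm, slice_mm = voxel_mm,
                       origin = NULL) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (is.null(origin))
    origin <- c(-n_x * voxel_mm / 2, -n_y * voxel_mm / 2, NA)
  list(n_x = n_x, n_y = n_y, voxel_mm = voxel_mm, slice_mm = slice_mm,
       origin = origin, spacing = c(voxel_mm, voxel_mm, slice_mm))
}

as_recon_grid <- function(grid, n_slices = 1L) {
  if (is_voxel_image(grid)) {
    d <- dim(grid$values)
    g <- recon_grid(d[1], d[2], grid$spacing[1], grid$spacing[3],
                    origin = grid$origin)
  } else g <- grid
  if (is.na(g$origin[3])) g$origin[3] <- -n_slices * g$slice_mm / 2
  g
}

#' Attenuation precorrection of a sinogram
#'
#' Multiplies measured data elementwise by the attenuation correction
#' factors, undoing attenuation in the sinogram domain before
#' reconstruction. The result is no longer Poisson distributed, so its kind
#' becomes `"line-integral"`.
#'
#' @param counts measured [sinogram()] (`"counts"` or `"line-integral"`).
#' @param acf an ACF [sinogram()] from [acf_sinogram()].
#' @return A [sinogram()] of kind `"line-integral"`.
#' @export
precorrect <- function(counts, acf) {
  stopifnot(is_sinogram(counts), is_sinogram(acf))
  if (acf$kind != "acf") stop("kind mismatch: 'acf' must be an ACF sinogram")
  if (!same_geometry(counts$geometry, acf$geometry) ||
      !identical(dim(counts$values), dim(acf$values)))
    stop("sinogram shapes/geometries do not match")
  sinogram(counts$values * acf$values, counts$geometry,
           kind = "line-integral")
}

#' 2D OSEM reconstruction
#'
#' Multiplicative ordered-subsets EM with interleaved angular subsets in a
#' fixed order, a uniform positive initial image, and a fixed iteration count
#' (no convergence test). The per-subset update is
#' `x <- x * backproject_s(y_s / forward_s(x)) / backproject_s(1)`, which
#' preserves nonnegativity. Voxels with zero sensitivity (never intersected
#' by a subset's rays) are masked out of the update rather than dividing by
#' zero. With `ac_mode = "system-matrix"` the forward model includes the
#' 1/ACF attenuation factors; with `"precorrected"` or `"none"` it is the
#' plain Radon transform (pass data through [precorrect()] yourself for the
#' former). Slices are reconstructed independently.
#'
#' @param data measured or precorrected [sinogram()], nonnegative.
#' @param grid target image grid ([recon_grid()] or template
#'   [voxel_image()]).
#' @param cfg a [recon_config()].
#' @param acf ACF [sinogram()], required iff `ac_mode = "system-matrix"`.
#' @return A [voxel_image()] (role `"activity"`).
#' @export
osem_reconstruct <- function(data, grid, cfg = recon_config(), acf = NULL) {
  stopifnot(is_sinogram(data), inherits(cfg, "recon_config"))
  if (any(data$values < 0)) stop("data sinogram must be nonnegative")
  geom <- data$geometry
  if (geom$n_angles %% cfg$n_subsets != 0L)
    stop(sprintf("n_angles (%d) must be divisible by n_subsets (%d)",
                 geom$n_angles, cfg$n_subsets))
  if (cfg$ac_mode == "system-matrix") {
    if (is.null(acf) || acf$kind != "acf")
      stop("ac_mode = 'system-matrix' requires an ACF sinogram")
  } else acf <- NULL
  d3 <- dim(data$values)[3]
  g <- as_recon_grid(grid, d3)
  A <- radon_matrix(geom, g$n_x, g$n_y, g$voxel_mm, g$origin[1:2])
  nb <- geom$n_bins
  # interleaved angular subsets, fixed order
  subsets <- lapply(seq_len(cfg$n_subsets), function(k) {
    angles <- seq(k, geom$n_angles, by = cfg$n_subsets)
    as.vector(outer(seq_len(nb), (angles - 1L) * nb, "+"))
  })
  As <- lapply(subsets, function(r) A[r, , drop = FALSE])
  # reconstruct only inside the radial FOV: voxels beyond it are sampled by
  # an incomplete angular subset and cannot be estimated consistently
  xs <- g$origin[1] + (seq_len(g$n_x) - 0.5) * g$voxel_mm
  ys <- g$origin[2] + (seq_len(g$n_y) - 0.5) * g$voxel_mm
  in_fov <- as.vector(outer(xs^2, ys^2, "+") <= (geom$fov_mm / 2)^2)
  out <- array(0, c(g$n_x, g$n_y, d3))
  for (sl in seq_len(d3)) {
    y <- as.numeric(t(data$values[, , sl]))
    w <- if (is.null(acf)) NULL else 1 / as.numeric(t(acf$values[, , sl]))
    sens <- vector("list", cfg$n_subsets)
    for (k in seq_len(cfg$n_subsets)) {
      wk <- if (is.null(w)) rep(1, length(subsets[[k]])) else w[subsets[[k]]]
      sens[[k]] <- as.numeric(Matrix::crossprod(As[[k]], wk))
    }
    mask <- Reduce(`+`, sens) > 0 & in_fov
    x <- ifelse(mask, cfg$init_value, 0)
    for (it in seq_len(cfg$n_iterations)) {
      for (k in seq_len(cfg$n_subsets)) {
        rows <- subsets[[k]]
        yhat <- as.numeric(As[[k]] %*% x)
        if (!is.null(w)) yhat <- yhat * w[rows]
        ratio <- numeric(length(yhat))
        pos <- yhat > 0
        ratio[pos] <- y[rows][pos] / yhat[pos]
        if (!is.null(w)) ratio <- ratio * w[rows]
        upd <- as.numeric(Matrix::crossprod(As[[k]], ratio))
        idx <- mask & sens[[k]] > 0
        x[idx] <- x[idx] * upd[idx] / sens[[k]][idx]
      }
    }
    out[, , sl] <- matrix(x, g$n_x, g$n_y)
  }
  voxel_image(out, g$spacing, g$origin, role = "activity")
}

# Poisson log-likelihood of sinogram data under the image's forward
# projection (up to the data-only lfactorial term). Used by the monotonicity
# tests.
poisson_loglik <- function(data, image, acf = NULL) {
  p <- radon_forward(image, data$geometry)
  lam <- if (is.null(acf)) p$values else p$values / acf$values
  keep <- lam > 0
  if (any(data$values[!keep] > 0)) return(-Inf)
  sum(data$values[keep] * log(lam[keep]) - lam[keep])
}
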