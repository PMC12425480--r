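#' Density volume container
#'
#' A 3D scalar grid in physical coordinates. Values are stored as an R array
#' indexed `[x, y, z]` (column-major, x fastest, matching MRC disk order).
#' The world coordinate of the voxel with 1-based index `(i, j, k)` is
#' `origin + (i - 1, j - 1, k - 1) * voxel_size`, i.e. `origin` is the world
#' position of the first voxel center, in nanometers.
#'
#' @param values 3D numeric array.
#' @param voxel_size voxel edge length(s) in nm; scalar or length-3.
#' @param origin world position (nm) of the center of voxel (1,1,1).
#' @return an object of class `density_volume`.
#' @export
density_volume <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be > 0")
  structure(
    list(values = values, voxel_size = voxel_size,
         origin = rep_len(as.numeric(origin), 3L)),
    class = "density_volume"
  )
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_volume> %d x %d x %d voxels, %.4g x %.4g x %.4g nm/voxel\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (nm): %.3f %.3f %.3f  range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' World extent of a volume
#'
#' @param vol a [density_volume].
#' @return 2x3 matrix; rows are the lower/upper world coordinates (nm) of the
#'   outer voxel faces.
#' @export
volume_extent <- function(vol) {
  d <- dim(vol$values)
  lo <- vol$origin - vol$voxel_size / 2
  hi <- vol$origin + (d - 1 + 0.5) * vol$voxel_size
  rbind(lo = lo, hi = hi)
}

#' Trilinear interpolation of a density volume at world points
#'
#' Points outside the grid return `NA` (masked), never an error.
#'
#' @param vol a [density_volume].
#' @param pts N x 3 matrix of world coordinates (nm).
#' @return numeric vector of length N.
#' @export
sample_volume <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  d <- dim(vol$values)
  # fractional 0-based voxel coordinates
  f <- sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$voxel_size, "/")
  i0 <- floor(f)
  w <- f - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  # allow points in the outer half-voxel shell by clamping the cell, keeping
  # the hard boundary at the voxel-center bounding box
  edge <- f[, 1] >= 0 - 1e-9 & f[, 2] >= 0 - 1e-9 & f[, 3] >= 0 - 1e-9 &
    f[, 1] <= d[1] - 1 + 1e-9 & f[, 2] <= d[2] - 1 + 1e-9 & f[, 3] <= d[3] - 1 + 1e-9
  use <- ok | edge
  out <- rep(NA_real_, nrow(pts))
  if (!any(use)) return(out)
  i0c <- pmin(pmax(i0[use, , drop = FALSE], 0), rep(d - 2, each = sum(use)))
  wc <- f[use, , drop = FALSE] - i0c
  wc <- pmin(pmax(wc, 0), 1)
  v <- vol$values
  ix <- i0c[, 1] + 1L; iy <- i0c[, 2] + 1L; iz <- i0c[, 3] + 1L
  idx <- function(dx, dy, dz) cbind(ix + dx, iy + dy, iz + dz)
  out[use] <-
    v[idx(0L, 0L, 0L)] * (1 - wc[, 1]) * (1 - wc[, 2]) * (1 - wc[, 3]) +
    v[idx(1L, 0L, 0L)] * wc[, 1] * (1 - wc[, 2]) * (1 - wc[, 3]) +
    v[idx(0L, 1L, 0L)] * (1 - wc[, 1]) * wc[, 2] * (1 - wc[, 3]) +
    v[idx(0L, 0L, 1L)] * (1 - wc[, 1]) * (1 - wc[, 2]) * wc[, 3] +
    v[idx(1L, 1L, 0L)] * wc[, 1] * wc[, 2] * (1 - wc[, 3]) +
    v[idx(1L, 0L, 1L)] * wc[, 1] * (1 - wc[, 2]) * wc[, 3] +
    v[idx(0L, 1L, 1L)] * (1 - wc[, 1]) * wc[, 2] * wc[, 3] +
    v[idx(1L, 1L, 1L)] * wc[, 1] * wc[, 2] * wc[, 3]
  out
}

#' Gaussian smoothing of a volume (FFT, periodic boundaries)
#'
#' @param vol a [density_volume] or 3D array.
#' @param sigma_vox isotropic Gaussian sigma in voxels; 0 returns the input.
#' @return same type as the input.
#' @export
smooth_volume <- function(vol, sigma_vox = 1) {
  arr <- if (inherits(vol, "density_volume")) vol$values else vol
  if (sigma_vox > 0) {
    d <- dim(arr)
    g1 <- function(n) {
      x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
      k <- exp(-x^2 / (2 * sigma_vox^2))
      k / sum(k)
    }
    K <- outer(outer(g1(d[1]), g1(d[2])), g1(d[3]))
    dim(K) <- d
    arr <- Re(fft(fft(arr) * fft(K), inverse = TRUE)) / prod(d)
  }
  if (inherits(vol, "density_volume")) {
    vol$values <- arr
    vol
  } else arr
}

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("points must be N x 3")
  storage.mode(pts) <- "double"
  pts
}
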