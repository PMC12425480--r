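#' Analytic mesh fixtures
#'
#' Generators for planar and curved reference meshes used throughout the
#' synthetic module and the test suite: flat sheets, discs with optional
#' lamellar tongue, spheres, and cylinders.
#'
#' @name mesh_primitives
NULL

#' Flat rectangular sheet mesh in the z = z0 plane
#'
#' Vertices lie on a regular grid, squares split along one diagonal, normals
#' oriented +z.
#'
#' @param extent_x,extent_y side lengths (nm).
#' @param spacing grid spacing (nm).
#' @param center length-3 world center of the sheet (nm).
#' @return a [tri_mesh].
#' @export
flat_square_mesh <- function(extent_x, extent_y = extent_x, spacing = 4,
                             center = c(0, 0, 0)) {
  if (extent_x <= 0 || extent_y <= 0) stop("sheet extent must be > 0")
  nx <- max(2L, round(extent_x / spacing) + 1L)
  ny <- max(2L, round(extent_y / spacing) + 1L)
  xs <- seq(-extent_x / 2, extent_x / 2, length.out = nx) + center[1]
  ys <- seq(-extent_y / 2, extent_y / 2, length.out = ny) + center[2]
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), center[3])
  id <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  # split so triangle normals (CCW seen from +z) point +z
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  tri_mesh(v, f)
}

#' Planar mesh over an arbitrary 2D region
#'
#' Triangulates the grid squares whose four corners satisfy `inside(x, y)`;
#' the boundary is therefore jagged at the `spacing` scale (boundary faces
#' are excluded from domain statistics downstream).
#'
#' @param inside vectorized predicate `function(x, y)` in world nm.
#' @param bbox c(xmin, xmax, ymin, ymax) bounding box (nm).
#' @param spacing grid spacing (nm).
#' @param z plane height (nm).
#' @return a [tri_mesh] with +z normals.
#' @export
grid_region_mesh <- function(inside, bbox, spacing = 4, z = 0) {
  xs <- seq(bbox[1], bbox[2], by = spacing)
  ys <- seq(bbox[3], bbox[4], by = spacing)
  nx <- length(xs); ny <- length(ys)
  keep_v <- outer(xs, ys, inside)
  id <- matrix(0L, nx, ny)
  sel <- which(keep_v)
  id[sel] <- seq_along(sel)
  v <- cbind(rep(xs, times = ny)[sel], rep(ys, each = nx)[sel], z)
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  c00 <- id[cbind(i, j)]; c10 <- id[cbind(i + 1L, j)]
  c11 <- id[cbind(i + 1L, j + 1L)]; c01 <- id[cbind(i, j + 1L)]
  ok <- c00 > 0L & c10 > 0L & c11 > 0L & c01 > 0L
  f <- rbind(cbind(c00[ok], c10[ok], c11[ok]),
             cbind(c00[ok], c11[ok], c01[ok]))
  if (nrow(f) == 0L) stop("region contains no complete grid square")
  tri_mesh(v, f)
}

#' Disc mesh, optionally with a lamellar tongue
#'
#' A planar disc of radius `radius` centered at `center`; when
#' `tongue_length > 0` a rectangular tongue of width `tongue_width` extends
#' in +x from the disc edge (the shape used for the phantom's non-appressed
#' lamellae).
#'
#' @param radius disc radius (nm).
#' @param spacing mesh grid spacing (nm).
#' @param center length-3 world center (nm).
#' @param tongue_length,tongue_width tongue dimensions (nm).
#' @return a [tri_mesh].
#' @export
disc_mesh <- function(radius, spacing = 4, center = c(0, 0, 0),
                      tongue_length = 0, tongue_width = radius) {
  cx <- center[1]; cy <- center[2]
  inside <- function(x, y) {
    d <- (x - cx)^2 + (y - cy)^2 <= radius^2
    if (tongue_length > 0) {
      d <- d | (x >= cx & x <= cx + radius + tongue_length &
                  abs(y - cy) <= tongue_width / 2)
    }
    d
  }
  bbox <- c(cx - radius - spacing, cx + radius + tongue_length + spacing,
            cy - radius - spacing, cy + radius + spacing)
  grid_region_mesh(inside, bbox, spacing = spacing, z = center[3])
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdiv` times with vertices projected to the
#' sphere; the standard nearly-uniform sphere triangulation.
#'
#' @param radius sphere radius (nm).
#' @param subdiv number of 1-to-4 subdivisions (0 = icosahedron).
#' @param center world center (nm).
#' @return a [tri_mesh] with outward normals.
#' @export
icosphere_mesh <- function(radius, subdiv = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  m <- tri_mesh(v / sqrt(1 + phi^2), f)
  for (i in seq_len(subdiv)) {
    m <- subdivide_mesh(m)
    m$vertices <- m$vertices / sqrt(rowSums(m$vertices^2))
    m <- tri_mesh(m$vertices, m$faces)
  }
  v <- m$vertices * radius
  v <- sweep(v, 2, center, "+")
  m <- tri_mesh(v, m$faces)
  # orient all faces outward
  ctr <- face_centroids(m) - matrix(center, nrow(m$faces), 3, byrow = TRUE)
  flip <- rowSums(ctr * m$normals) < 0
  if (any(flip)) {
    fz <- m$faces
    fz[flip, ] <- fz[flip, c(1, 3, 2)]
    m <- tri_mesh(m$vertices, fz)
  }
  m
}

#' Open cylinder mesh (no caps)
#'
#' @param radius,height cylinder dimensions (nm); axis along z.
#' @param n_around,n_along grid resolution.
#' @return a [tri_mesh] with outward normals.
#' @export
cylinder_mesh <- function(radius, height, n_around = 48, n_along = 16) {
  th <- seq(0, 2 * pi, length.out = n_around + 1L)[-(n_around + 1L)]
  zs <- seq(-height / 2, height / 2, length.out = n_along)
  v <- cbind(radius * cos(rep(th, times = n_along)),
             radius * sin(rep(th, times = n_along)),
             rep(zs, each = n_around))
  id <- function(i, j) (j - 1L) * n_around + ((i - 1L) %% n_around) + 1L
  i <- rep(seq_len(n_around), times = n_along - 1L)
  j <- rep(seq_len(n_along - 1L), each = n_around)
  f <- rbind(cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
             cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
  tri_mesh(v, f)
}
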