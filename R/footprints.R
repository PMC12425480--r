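#' In-plane footprint of a photosynthetic complex
#'
#' A footprint is the closed 2D outline a complex occupies in the membrane
#' plane, in a local frame whose origin is the particle center and whose +x
#' axis is the orientation reference. Built-in variants are documented
#' geometric approximations with realistic overall dimensions (they are not
#' measured outlines): the PSII core dimer `C2` (elliptical, 20.5 x 11 nm),
#' the `C2S2` supercomplex (24 x 13 nm), the `C2S2M2` supercomplex
#' (rounded-rectangular, 30.5 x 13.5 nm), the pair of strongly bound LHCII
#' trimers `S2_trimers_only` (two 7.6 nm discs bridged at the dimer
#' positions), and the cytochrome b6f dimer `cytb6f` (9 x 6.2 nm).
#' Alternatively the outline is derived from an atomic structure: atoms in
#' the membrane slab are projected onto the xy plane, blurred to 14 A
#' resolution, contoured at half maximum, and the largest closed contour is
#' taken.
#'
#' @param variant one of `C2`, `C2S2`, `C2S2M2`, `S2_trimers_only`,
#'   `cytb6f`.
#' @param structure_file optional PDB file; when given the outline is
#'   derived from the structure (requires the `bio3d` package) and
#'   `variant` is only a label. The structure must already be aligned with
#'   the membrane plane = xy.
#' @param scale isotropic scale factor applied to built-in outlines.
#' @param slab_nm half-thickness of the membrane slab used to select atoms
#'   (structure mode).
#' @return object of class `footprint`: `variant`, `outline` (k x 2 matrix,
#'   closed implicitly), `area` (nm^2), `provenance`.
#' @export
make_footprint <- function(variant = c("C2", "C2S2", "C2S2M2",
                                       "S2_trimers_only", "cytb6f"),
                           structure_file = NULL, scale = 1,
                           slab_nm = 2.5) {
  variant <- match.arg(variant)
  if (!is.null(structure_file))
    return(footprint_from_structure(variant, structure_file, slab_nm))
  outline <- switch(variant,
    C2 = ellipse_outline(20.5 / 2, 11 / 2),
    C2S2 = ellipse_outline(24 / 2, 13 / 2),
    C2S2M2 = superellipse_outline(30.5 / 2, 13.5 / 2, p = 2.5),
    S2_trimers_only = dumbbell_outline(disc_r = 3.8, offset = 8.5,
                                       waist = 2.6),
    cytb6f = ellipse_outline(9 / 2, 6.2 / 2))
  outline <- outline * scale
  fp <- structure(list(variant = variant, outline = outline,
                       area = polygon_area(outline),
                       provenance = "builtin"),
                  class = "footprint")
  validate_footprint(fp)
  fp
}

validate_footprint <- function(fp) {
  if (fp$area <= 0) stop("footprint area must be > 0")
  if (!point_in_polygon_single(c(0, 0), fp$outline))
    stop("footprint outline must contain the origin")
  invisible(fp)
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("<footprint> %s (%s), %d vertices, area %.1f nm^2\n",
              x$variant, x$provenance, nrow(x$outline), x$area))
  invisible(x)
}

ellipse_outline <- function(a, b, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

superellipse_outline <- function(a, b, p = 2.5, n = 32) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * sign(cos(th)) * abs(cos(th))^(2 / p),
        b * sign(sin(th)) * abs(sin(th))^(2 / p))
}

# two discs bridged by a waist; a simple (star-shaped) polygon containing
# the origin between the discs
dumbbell_outline <- function(disc_r, offset, waist) {
  th_r <- seq(-2, 2, length.out = 13) / 2 * pi / 2 * 1.4  # about +/-126 deg
  right <- cbind(offset + disc_r * cos(th_r), disc_r * sin(th_r))
  left <- cbind(-offset - disc_r * cos(th_r), disc_r * sin(th_r))
  top_l <- c(-offset + disc_r * cos(th_r[1]) * 0.2, waist / 2)
  top_r <- c(offset - disc_r * cos(th_r[1]) * 0.2, waist / 2)
  poly <- rbind(right[order(th_r), ],
                rbind(c(top_r[1], waist / 2), c(top_l[1], waist / 2)),
                left[order(-th_r), ],
                rbind(c(top_l[1], -waist / 2), c(top_r[1], -waist / 2)))
  poly
}

footprint_from_structure <- function(variant, structure_file, slab_nm) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("structure-derived footprints require the bio3d package")
  pdb <- tryCatch(bio3d::read.pdb(structure_file),
                  error = function(e) stop("cannot parse structure file ",
                                           structure_file, ": ",
                                           conditionMessage(e)))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  xyz <- sweep(xyz, 2, colMeans(xyz), "-")
  sel <- abs(xyz[, 3]) <= slab_nm
  if (sum(sel) < 10) stop("fewer than 10 atoms inside the membrane slab")
  xy <- xyz[sel, 1:2, drop = FALSE]
  # 2D density at 0.5 nm pixels, blurred to 14 A resolution
  px <- 0.5
  pad <- 3
  xr <- range(xy[, 1]) + c(-pad, pad); yr <- range(xy[, 2]) + c(-pad, pad)
  gx <- seq(xr[1], xr[2], by = px); gy <- seq(yr[1], yr[2], by = px)
  H <- matrix(0, length(gx), length(gy))
  ix <- findInterval(xy[, 1], gx); iy <- findInterval(xy[, 2], gy)
  for (i in seq_len(nrow(xy))) H[ix[i], iy[i]] <- H[ix[i], iy[i]] + 1
  sg <- (1.4 / 2.355) / px
  k <- dnorm(seq(-ceiling(4 * sg), ceiling(4 * sg)), sd = sg)
  k <- k / sum(k)
  H <- apply(H, 2, function(cl) stats::filter(cl, k, circular = TRUE))
  H <- t(apply(H, 1, function(rw) stats::filter(rw, k, circular = TRUE)))
  cl <- grDevices::contourLines(gx, gy, H, levels = max(H) / 2)
  if (length(cl) == 0) stop("no closed contour at half maximum")
  areas <- vapply(cl, function(cc) polygon_area(cbind(cc$x, cc$y)), 0)
  best <- cl[[which.max(areas)]]
  closed <- abs(best$x[1] - best$x[length(best$x)]) < 1e-9 &&
    abs(best$y[1] - best$y[length(best$y)]) < 1e-9
  if (!closed) stop("half-maximum contour is open")
  outline <- cbind(best$x, best$y)
  outline <- outline[-nrow(outline), , drop = FALSE]
  outline <- sweep(outline, 2, polygon_centroid(outline), "-")
  fp <- structure(list(variant = variant, outline = outline,
                       area = polygon_area(outline),
                       provenance = "derived-from-structure"),
                  class = "footprint")
  validate_footprint(fp)
  fp
}

# ---- polygon utilities -----------------------------------------------------

#' Polygon area (shoelace), rotation, and point membership
#'
#' Small exact-geometry helpers used by the occupancy module.
#'
#' @param poly k x 2 matrix of polygon vertices (closed implicitly).
#' @return `polygon_area`: area (always >= 0).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @rdname polygon_area
#' @param degrees rotation angle.
#' @export
rotate_polygon <- function(poly, degrees) {
  th <- degrees * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  poly %*% t(R)
}

point_in_polygon_single <- function(p, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > p[2]) != (poly[j, 2] > p[2]) &&
        p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# ensure counter-clockwise orientation
ccw_polygon <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# ear-clipping triangulation of a simple polygon; returns list of 3 x 2
# triangle matrices
triangulate_polygon <- function(poly) {
  poly <- ccw_polygon(poly)
  idx <- seq_len(nrow(poly))
  tris <- list()
  guard <- 0L
  while (length(idx) > 3L && guard < 10000L) {
    guard <- guard + 1L
    n <- length(idx)
    clipped <- FALSE
    for (k in seq_len(n)) {
      i0 <- idx[(k - 2L) %% n + 1L]
      i1 <- idx[(k - 1L) %% n + 1L]
      i2 <- idx[k %% n + 1L]
      a <- poly[i0, ]; b <- poly[i1, ]; c2 <- poly[i2, ]
      cross <- (b[1] - a[1]) * (c2[2] - a[2]) - (b[2] - a[2]) * (c2[1] - a[1])
      if (cross <= 1e-12) next  # reflex or degenerate
      # no other polygon vertex inside the candidate ear
      tri <- rbind(a, b, c2)
      others <- setdiff(idx, c(i0, i1, i2))
      bad <- FALSE
      for (o in others) {
        if (point_in_triangle2(poly[o, ], tri)) { bad <- TRUE; break }
      }
      if (bad) next
      tris[[length(tris) + 1L]] <- tri
      idx <- setdiff(idx, i1)
      clipped <- TRUE
      break
    }
    if (!clipped) break  # numerically stuck; remaining polygon is convex-ish
  }
  if (length(idx) >= 3L) {
    rem <- poly[idx, , drop = FALSE]
    for (k in 2:(nrow(rem) - 1L))
      tris[[length(tris) + 1L]] <- rbind(rem[1, ], rem[k, ], rem[k + 1L, ])
  }
  tris
}

point_in_triangle2 <- function(p, tri) {
  s <- function(a, b) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  d1 <- s(tri[1, ], tri[2, ]); d2 <- s(tri[2, ], tri[3, ]); d3 <- s(tri[3, ], tri[1, ])
  (d1 > 1e-12 & d2 > 1e-12 & d3 > 1e-12) |
    (d1 < -1e-12 & d2 < -1e-12 & d3 < -1e-12)
}

# Sutherland-Hodgman clip of polygon `subject` by CONVEX polygon `clip`
convex_clip <- function(subject, clip) {
  clip <- ccw_polygon(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[i %% nc + 1L, ]
    inp <- out
    n <- nrow(inp)
    keep <- ((b[1] - a[1]) * (inp[, 2] - a[2]) -
               (b[2] - a[2]) * (inp[, 1] - a[1])) >= -1e-12
    res <- matrix(0, 0, 2)
    for (j in seq_len(n)) {
      jn <- j %% n + 1L
      p1 <- inp[j, ]; p2 <- inp[jn, ]
      if (keep[j]) res <- rbind(res, p1)
      if (keep[j] != keep[jn]) {
        den <- (b[1] - a[1]) * (p2[2] - p1[2]) - (b[2] - a[2]) * (p2[1] - p1[1])
        if (abs(den) > 1e-15) {
          t <- ((b[1] - a[1]) * (a[2] - p1[2]) -
                  (b[2] - a[2]) * (a[1] - p1[1])) / den
          t <- min(max(t, 0), 1)
          res <- rbind(res, p1 + t * (p2 - p1))
        }
      }
    }
    out <- res
  }
  if (is.null(out) || nrow(out) < 3) NULL else out
}

#' Exact intersection area of two simple polygons
#'
#' Both polygons are partitioned into triangles (ear clipping) and all
#' triangle pairs are clipped with the Sutherland-Hodgman algorithm; the
#' intersection area is the sum over pairs.
#'
#' @param p1,p2 k x 2 polygon matrices.
#' @return intersection area.
#' @export
polygon_intersection_area <- function(p1, p2) {
  # quick bounding-box rejection
  if (max(p1[, 1]) < min(p2[, 1]) || max(p2[, 1]) < min(p1[, 1]) ||
      max(p1[, 2]) < min(p2[, 2]) || max(p2[, 2]) < min(p1[, 2]))
    return(0)
  t1 <- triangulate_polygon(p1)
  t2 <- triangulate_polygon(p2)
  total <- 0
  for (a in t1) for (b in t2) {
    cl <- convex_clip(a, b)
    if (!is.null(cl)) total <- total + polygon_area(cl)
  }
  total
}
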