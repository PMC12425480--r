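#' Membrane-plane frame for footprint geometry
#'
#' Footprint placement, clash, and coverage are computed in a 2D frame in
#' the membrane's best-fit plane (tangent-plane geometry; appressed grana
#' membranes are near-planar at footprint scale). The in-plane axes follow
#' a fixed convention (+x = world x projected into the plane), and the
#' raster grid used for union areas is anchored to the particle pattern's
#' own principal axis and centroid, so that a rigid rotation of mesh and
#' particles together changes no statistic beyond floating-point noise.
#'
#' @param mesh a [tri_mesh].
#' @return list `origin`, `e1`, `e2`, `normal`.
#' @export
membrane_frame <- function(mesh) {
  ctr <- colMeans(mesh$vertices)
  sv <- svd(sweep(mesh$vertices, 2, ctr, "-"), nu = 0, nv = 3)
  n <- sv$v[, 3]
  if (sum(n * colMeans(mesh$normals)) < 0) n <- -n
  e1 <- c(1, 0, 0) - n[1] * n
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(0, 1, 0) - n[2] * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(origin = ctr, e1 = e1, e2 = e2, normal = n)
}

frame_uv <- function(frame, pts) {
  rel <- sweep(as_point_matrix(pts), 2, frame$origin, "-")
  cbind(rel %*% frame$e1, rel %*% frame$e2)
}

#' Place footprints at particle positions
#'
#' Each footprint polygon is rotated by the particle's in-plane angle and
#' translated to the particle position, all in the membrane frame.
#' Particles with missing orientation are placed unrotated and flagged
#' (they are excluded from clash statistics).
#'
#' @param particles a [particle_set()].
#' @param footprint a [make_footprint()] result.
#' @param mesh the membrane [tri_mesh].
#' @param frame optional precomputed [membrane_frame()].
#' @return object of class `placed_footprints`: list of 2D polygons
#'   (`polys`), particle table, `frame`, `footprint`, `no_orientation`
#'   flags.
#' @export
place_footprints <- function(particles, footprint, mesh,
                             frame = membrane_frame(mesh)) {
  uv <- if (nrow(particles)) frame_uv(frame, particle_positions(particles))
        else matrix(0, 0, 2)
  polys <- vector("list", nrow(particles))
  noori <- is.na(particles$angle)
  for (i in seq_len(nrow(particles))) {
    ang <- if (noori[i]) 0 else particles$angle[i]
    polys[[i]] <- sweep(rotate_polygon(footprint$outline, ang), 2,
                        uv[i, ], "+")
  }
  structure(list(polys = polys, particles = particles, frame = frame,
                 footprint = footprint, no_orientation = noori,
                 mesh_area = mesh_area(mesh)),
            class = "placed_footprints")
}

#' In-plane steric clash between placed footprints
#'
#' Sum of pairwise footprint intersection areas (exact polygon clipping)
#' divided by the total footprint area, i.e. the percent overlap of total
#' footprint area. Footprints without orientation are excluded.
#'
#' @param placed a [place_footprints()] result.
#' @return list `clash_fraction`, `pair_area` (summed intersection, nm^2),
#'   `total_area`.
#' @export
in_plane_clash <- function(placed) {
  keep <- which(!placed$no_orientation)
  polys <- placed$polys[keep]
  n <- length(polys)
  if (n < 2)
    return(list(clash_fraction = 0, pair_area = 0,
                total_area = n * placed$footprint$area))
  ctr <- t(vapply(polys, polygon_centroid, numeric(2)))
  rad <- vapply(polys, function(p)
    sqrt(max(rowSums(sweep(p, 2, polygon_centroid(p), "-")^2))), 0)
  pair_area <- 0
  for (i in seq_len(n - 1L)) {
    d2 <- (ctr[(i + 1):n, 1] - ctr[i, 1])^2 + (ctr[(i + 1):n, 2] - ctr[i, 2])^2
    cand <- which(d2 <= (rad[i] + rad[(i + 1):n])^2) + i
    for (j in cand)
      pair_area <- pair_area + polygon_intersection_area(polys[[i]],
                                                         polys[[j]])
  }
  total <- n * placed$footprint$area
  list(clash_fraction = pair_area / total, pair_area = pair_area,
       total_area = total)
}

# ---- raster engine ---------------------------------------------------------

# Deterministic raster frame: axes along the principal direction of the
# polygon centroids (sign fixed by the first polygon), origin at their mean.
raster_frame2d <- function(polys) {
  if (length(polys) == 0) return(list(R = diag(2), origin = c(0, 0)))
  ctr <- t(vapply(polys, polygon_centroid, numeric(2)))
  org <- colMeans(ctr)
  if (nrow(ctr) < 3) return(list(R = diag(2), origin = org))
  cv <- stats::cov(ctr)
  if (!all(is.finite(cv)) || abs(cv[1, 2]) + abs(cv[1, 1] - cv[2, 2]) < 1e-9)
    return(list(R = diag(2), origin = org))
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (sum((ctr[1, ] - org) * ev) < 0) ev <- -ev
  R <- rbind(c(ev[1], ev[2]), c(-ev[2], ev[1]))
  list(R = R, origin = org)
}

# rasterize polygons into a logical grid; returns grid + mask
raster_union <- function(polys, resolution = 0.5, frame2d = NULL,
                         bbox = NULL) {
  if (is.null(frame2d)) frame2d <- raster_frame2d(polys)
  tp <- lapply(polys, function(p)
    sweep(p, 2, frame2d$origin, "-") %*% t(frame2d$R))
  if (is.null(bbox)) {
    allp <- do.call(rbind, tp)
    bbox <- c(min(allp[, 1]) - resolution, max(allp[, 1]) + resolution,
              min(allp[, 2]) - resolution, max(allp[, 2]) + resolution)
  }
  gx <- seq(bbox[1], bbox[2], by = resolution)
  gy <- seq(bbox[3], bbox[4], by = resolution)
  mask <- matrix(FALSE, length(gx), length(gy))
  for (p in tp) {
    xi <- which(gx >= min(p[, 1]) - resolution & gx <= max(p[, 1]) + resolution)
    yi <- which(gy >= min(p[, 2]) - resolution & gy <= max(p[, 2]) + resolution)
    if (!length(xi) || !length(yi)) next
    sub <- fill_polygon_grid(p, gx[xi], gy[yi])
    mask[xi, yi] <- mask[xi, yi] | sub
  }
  list(mask = mask, gx = gx, gy = gy, resolution = resolution,
       frame2d = frame2d, bbox = bbox)
}

# scanline point-in-polygon over a grid (even-odd rule, vectorized per row)
fill_polygon_grid <- function(poly, gx, gy) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  out <- matrix(FALSE, length(gx), length(gy))
  for (j in seq_along(gy)) {
    yp <- gy[j]
    cr <- (y1 > yp) != (y2 > yp)
    if (!any(cr)) next
    xs <- x1[cr] + (yp - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr])
    xs <- sort(xs)
    inside <- rep(FALSE, length(gx))
    for (k in seq(1, length(xs) - 1, by = 2))
      inside <- inside | (gx > xs[k] & gx < xs[k + 1])
    out[, j] <- inside
  }
  out
}

raster_area <- function(r) sum(r$mask) * r$resolution^2

#' Membrane coverage by placed footprints
#'
#' Union area of the footprints (rasterized at `resolution`; clashes are
#' not double-counted) divided by the analyzed membrane area.
#'
#' @param placed a [place_footprints()] result.
#' @param resolution raster pixel (nm).
#' @param analyzed_area area denominator (nm^2); defaults to the mesh area.
#' @param region optional raster region (from [project_stack()]) restricting
#'   the analysis to the area shared by all projected membranes.
#' @return list `covered_fraction`, `union_area`, `analyzed_area`.
#' @export
membrane_coverage <- function(placed, resolution = 0.5,
                              analyzed_area = placed$mesh_area,
                              region = NULL) {
  if (analyzed_area <= 0) stop("analyzed membrane area is zero")
  if (length(placed$polys) == 0)
    return(list(covered_fraction = 0, union_area = 0,
                analyzed_area = analyzed_area))
  if (is.null(region)) {
    r <- raster_union(placed$polys, resolution)
    ua <- raster_area(r)
  } else {
    r <- raster_union(placed$polys, region$resolution,
                      frame2d = region$frame2d, bbox = region$bbox)
    ua <- sum(r$mask & region$mask) * region$resolution^2
  }
  list(covered_fraction = ua / analyzed_area, union_area = ua,
       analyzed_area = analyzed_area)
}

#' Project particle sets across a membrane stack onto the first membrane
#'
#' The stack axis is the average face normal of the starting membrane.
#' Particle positions of every membrane are translated along this axis onto
#' the starting mesh (ray casting; particles whose projection misses the
#' mesh are dropped and counted). In-plane orientations are preserved. The
#' analysis region is restricted to the area shared by all projected
#' membrane outlines.
#'
#' @param meshes ordered list of [tri_mesh] (first = reference).
#' @param particle_sets list of [particle_set()], parallel to `meshes`.
#' @param resolution raster resolution for the shared-region mask (nm).
#' @return list: `particles` (projected sets), `frame`, `region` (raster
#'   mask of the shared area with `area_nm2`), `dropped` (count per set).
#' @export
project_stack <- function(meshes, particle_sets, resolution = 0.5) {
  ref <- meshes[[1]]
  frame <- membrane_frame(ref)
  axis <- colSums(ref$normals * ref$areas)
  axis <- axis / sqrt(sum(axis^2))
  # pre: membranes roughly parallel
  for (m in meshes) {
    nb <- colSums(m$normals * m$areas)
    nb <- nb / sqrt(sum(nb^2))
    if (acos(min(1, abs(sum(nb * axis)))) > 30 * pi / 180)
      warning("membrane deviates more than 30 degrees from the stack axis")
  }
  out_sets <- vector("list", length(particle_sets))
  dropped <- integer(length(particle_sets))
  for (k in seq_along(particle_sets)) {
    ps <- particle_sets[[k]]
    if (nrow(ps) == 0) { out_sets[[k]] <- ps; next }
    P <- particle_positions(ps)
    hit <- .trace_rays(P, matrix(axis, nrow(P), 3, byrow = TRUE),
                       ref$vertices, ref$faces,
                       rep(list(integer(0)), nrow(P)), eps = -1)
    ok <- is.finite(hit$distance)
    dropped[k] <- sum(!ok)
    if (any(!ok))
      message(sprintf("project_stack: %d particle(s) of set %d missed the reference mesh",
                      sum(!ok), k))
    ps <- ps[ok, , drop = FALSE]
    P <- P[ok, , drop = FALSE]
    tt <- hit$distance[ok]
    # signed translation: choose the sign that lands on the reference mesh
    Pp <- P + tt * matrix(axis, nrow(P), 3, byrow = TRUE)
    Pm <- P - tt * matrix(axis, nrow(P), 3, byrow = TRUE)
    dp <- abs(sweep(Pp, 2, frame$origin, "-") %*% frame$normal)
    dm <- abs(sweep(Pm, 2, frame$origin, "-") %*% frame$normal)
    Pn <- ifelse(matrix(dp <= dm, nrow(P), 3), Pp, Pm)
    ps$x <- Pn[, 1]; ps$y <- Pn[, 2]; ps$z <- Pn[, 3]
    out_sets[[k]] <- particle_set(ps)
  }
  # shared region: intersection of all projected membrane outlines
  proj_faces <- lapply(meshes, function(m) {
    uv <- frame_uv(frame, project_along(m$vertices, axis, frame))
    lapply(seq_len(nrow(m$faces)), function(f) uv[m$faces[f, ], , drop = FALSE])
  })
  # raster frame anchored to the projected particle pattern (rotation
  # covariance); falls back to the frame axes when too few particles
  all_uv <- do.call(rbind, lapply(out_sets, function(ps)
    if (nrow(ps)) frame_uv(frame, particle_positions(ps)) else NULL))
  fr2 <- if (!is.null(all_uv) && nrow(all_uv) >= 3)
    raster_frame2d(lapply(seq_len(nrow(all_uv)),
                          function(i) all_uv[i, , drop = FALSE]))
  else raster_frame2d(list(frame_poly_bbox(proj_faces)))
  r0 <- raster_union(unlist(proj_faces, recursive = FALSE), resolution,
                     frame2d = fr2)
  shared <- r0$mask
  for (k in seq_along(proj_faces)[-1]) {
    rk <- raster_union(proj_faces[[k]], resolution, frame2d = fr2,
                       bbox = r0$bbox)
    shared <- shared & rk$mask
  }
  # the first union covered all meshes; recompute mesh 1 alone
  r1 <- raster_union(proj_faces[[1]], resolution, frame2d = fr2,
                     bbox = r0$bbox)
  shared <- shared & r1$mask
  region <- list(mask = shared, gx = r0$gx, gy = r0$gy,
                 resolution = resolution, frame2d = fr2, bbox = r0$bbox,
                 area_nm2 = sum(shared) * resolution^2)
  list(particles = out_sets, frame = frame, region = region,
       dropped = dropped, axis = axis)
}

project_along <- function(pts, axis, frame) {
  # oblique projection of points along `axis` onto the frame plane
  rel <- sweep(as_point_matrix(pts), 2, frame$origin, "-")
  t <- (rel %*% frame$normal) / sum(axis * frame$normal)
  sweep(as_point_matrix(pts) - t %*% rbind(axis), 2, c(0, 0, 0), "+")
}

frame_poly_bbox <- function(proj_faces) {
  allp <- do.call(rbind, unlist(proj_faces, recursive = FALSE))
  cbind(range(allp[, 1])[c(1, 2, 2, 1)], range(allp[, 2])[c(1, 1, 2, 2)])
}

#' Cumulative footprint coverage across a granum stack
#'
#' Running union-area fraction (within the shared region) after adding each
#' membrane's footprints in stack order; by construction non-decreasing.
#'
#' @param projected result of [project_stack()].
#' @param footprint a [make_footprint()] result.
#' @param resolution raster pixel (nm); the shared-region resolution is
#'   used.
#' @return numeric vector: covered fraction after each membrane.
#' @export
cumulative_coverage <- function(projected, footprint, resolution = NULL) {
  region <- projected$region
  res <- region$resolution
  acc <- matrix(FALSE, nrow(region$mask), ncol(region$mask))
  out <- numeric(length(projected$particles))
  for (k in seq_along(projected$particles)) {
    ps <- projected$particles[[k]]
    if (nrow(ps) > 0) {
      uv <- frame_uv(projected$frame, particle_positions(ps))
      polys <- lapply(seq_len(nrow(ps)), function(i)
        sweep(rotate_polygon(footprint$outline, ps$angle[i]), 2, uv[i, ], "+"))
      rk <- raster_union(polys, res, frame2d = region$frame2d,
                         bbox = region$bbox)
      acc <- acc | rk$mask
    }
    out[k] <- sum(acc & region$mask) / max(1, sum(region$mask))
  }
  out
}

#' Overlap between two sets across a gap
#'
#' Footprint mode: both particle sets are rasterized on the common
#' reference membrane and the overlap is area(A and B) / area(A), the
#' fraction of the first set's footprint area overlapped by the second.
#' Density mode: two membranograms (per-face masks on the same mesh) are
#' compared area-weighted, overlap = area(A and B) / area(A). Luminal and
#' stromal gaps are handled identically; `gap_type` is recorded.
#'
#' @param a,b either `placed_footprints` on a common frame (footprint mode)
#'   or `membranogram` objects on the same mesh (density mode).
#' @param mesh the common mesh (density mode only).
#' @param gap_type `"stromal"` or `"luminal"` (metadata).
#' @param region optional shared-area raster region (footprint mode).
#' @param resolution raster pixel (nm, footprint mode).
#' @param normalize `"first"` (per the reported percentages) or `"union"`.
#' @return list `overlap_fraction`, `gap_type`, `mode`,
#'   `restricted_to_shared` flag.
#' @export
pair_overlap <- function(a, b, mesh = NULL,
                         gap_type = c("stromal", "luminal"),
                         region = NULL, resolution = 0.5,
                         normalize = c("first", "union")) {
  gap_type <- match.arg(gap_type)
  normalize <- match.arg(normalize)
  if (inherits(a, "membranogram")) {
    stopifnot(inherits(b, "membranogram"), !is.null(mesh))
    ma <- a$mask & !is.na(a$values)
    mb <- b$mask & !is.na(b$values)
    area_a <- sum(mesh$areas[ma])
    area_ab <- sum(mesh$areas[ma & mb])
    den <- if (normalize == "first") area_a else sum(mesh$areas[ma | mb])
    frac <- if (den > 0) area_ab / den else 0
    return(list(overlap_fraction = frac, gap_type = gap_type,
                mode = "density", restricted_to_shared = FALSE))
  }
  stopifnot(inherits(a, "placed_footprints"), inherits(b, "placed_footprints"))
  polys <- c(a$polys, b$polys)
  fr2 <- if (!is.null(region)) region$frame2d else raster_frame2d(polys)
  res <- if (!is.null(region)) region$resolution else resolution
  bb <- if (!is.null(region)) region$bbox else {
    # bounding box in the raster frame's transformed coordinates
    allp <- sweep(do.call(rbind, polys), 2, fr2$origin, "-") %*% t(fr2$R)
    c(min(allp[, 1]) - res, max(allp[, 1]) + res,
      min(allp[, 2]) - res, max(allp[, 2]) + res)
  }
  ra <- raster_union(a$polys, res, frame2d = fr2, bbox = bb)
  rb <- raster_union(b$polys, res, frame2d = fr2, bbox = bb)
  ma <- ra$mask; mb <- rb$mask
  if (!is.null(region)) { ma <- ma & region$mask; mb <- mb & region$mask }
  den <- if (normalize == "first") sum(ma) else sum(ma | mb)
  frac <- if (den > 0) sum(ma & mb) / den else 0
  list(overlap_fraction = frac, gap_type = gap_type, mode = "footprint",
       restricted_to_shared = !is.null(region))
}

#' Render a membranogram
#'
#' Samples the volume at a fixed signed offset along each face normal
#' (default 2 nm above the surface) and paints the value onto the mesh.
#' Binarization splits the face-value histogram into two classes (1D
#' k-means); the threshold is the midpoint of the class centers.
#'
#' @param volume a [density_volume].
#' @param mesh the membrane [tri_mesh].
#' @param offset offset along the normal (nm); positive = along the face
#'   normals of the stated side.
#' @param side `"luminal"` or `"stromal"` (metadata; the caller orients the
#'   mesh normals toward the requested side).
#' @param direction +1 to sample along the face normal, -1 against it.
#' @param threshold binarization threshold; `NULL` uses the histogram
#'   split.
#' @return object of class `membranogram`: `values` per face (NA outside
#'   the volume), `mask` (logical above-threshold), `offset`, `side`,
#'   `threshold`.
#' @export
render_membranogram <- function(volume, mesh, offset = 2,
                                side = c("luminal", "stromal"),
                                direction = 1, threshold = NULL) {
  side <- match.arg(side)
  pts <- face_centroids(mesh) + direction * offset * mesh$normals
  vals <- sample_volume(volume, pts)
  ok <- !is.na(vals)
  if (is.null(threshold)) {
    v <- vals[ok]
    if (length(unique(v)) < 2 ||
        diff(range(v)) < 1e-9 * max(abs(v), 1)) {
      threshold <- Inf  # constant membranogram: nothing above threshold
    } else {
      km <- stats::kmeans(v, centers = range(v), iter.max = 50)
      threshold <- mean(km$centers)
    }
  }
  mask <- !is.na(vals) & vals > threshold
  structure(list(values = vals, mask = mask, offset = offset, side = side,
                 direction = direction, threshold = threshold),
            class = "membranogram")
}

#' @export
print.membranogram <- function(x, ...) {
  cat(sprintf(
    "<membranogram> %s side, %+.1f nm offset, %d/%d faces above threshold %.3g\n",
    x$side, x$direction * x$offset, sum(x$mask), length(x$values),
    x$threshold))
  invisible(x)
}
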