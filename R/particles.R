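#' Nearest-neighbor distances between particle classes on a membrane
#'
#' For each source-class particle, the distance to the nearest target-class
#' particle (excluding itself) on the same membrane. The default metric is
#' the mesh geodesic: candidate neighbors are pre-ranked by 3D chord
#' distance (a lower bound on the geodesic), and geodesics are evaluated
#' only for candidates that could still win. On a perfectly planar mesh the
#' geodesic equals the chord and the fast path is used directly. Clipped
#' particles are excluded as sources (their true nearest neighbor may lie
#' beyond the analyzed patch) but remain available as targets.
#'
#' @param particles a [particle_set()].
#' @param mesh the membrane [tri_mesh].
#' @param source_class,target_class class labels; `"all"` matches every
#'   class.
#' @param metric `"geodesic"`, `"chord"`, or `"graph"` (vertex Dijkstra
#'   upper bound).
#' @param include_clipped_sources keep clipped particles as sources.
#' @return object of class `nn_result`: `per_particle` data frame (source
#'   row index, target row index, distance nm) and `summary` (n, mean, sd,
#'   sem); attribute `flagged` is TRUE when fewer than 2 relevant particles
#'   were available.
#' @export
nn_distances <- function(particles, mesh, source_class = "all",
                         target_class = "all",
                         metric = c("geodesic", "chord", "graph"),
                         include_clipped_sources = FALSE) {
  metric <- match.arg(metric)
  src <- which((source_class == "all" | particles$class == source_class) &
                 (include_clipped_sources | !particles$clipped))
  tgt <- which(target_class == "all" | particles$class == target_class)
  if (length(src) == 0 || length(tgt) == 0 ||
      length(unique(c(src, tgt))) < 2) {
    out <- structure(list(per_particle = NULL, summary = NULL),
                     class = "nn_result")
    attr(out, "flagged") <- TRUE
    return(out)
  }
  P <- particle_positions(particles)
  planar <- is_planar_mesh(mesh)
  if (metric != "chord" && !planar) {
    # measure between on-surface positions so that the chord bound (and the
    # geodesic >= chord invariant) refers to the same points
    idx <- sort(unique(c(src, tgt)))
    P[idx, ] <- snap_to_mesh(mesh, P[idx, , drop = FALSE])$point
  }
  rows <- data.frame(source = src, target = NA_integer_,
                     distance = NA_real_)
  for (k in seq_along(src)) {
    i <- src[k]
    cand <- setdiff(tgt, i)
    if (length(cand) == 0) next
    dx <- P[cand, 1] - P[i, 1]; dy <- P[cand, 2] - P[i, 2]
    dz <- P[cand, 3] - P[i, 3]
    chord <- sqrt(dx * dx + dy * dy + dz * dz)
    if (metric == "chord" || (metric == "geodesic" && planar)) {
      j <- which.min(chord)
      rows$target[k] <- cand[j]
      rows$distance[k] <- chord[j]
      next
    }
    ord <- order(chord)
    best <- Inf; bestj <- NA_integer_
    for (j in ord) {
      if (chord[j] >= best) break  # geodesic >= chord: cannot win
      d <- geodesic_distance(mesh, P[i, ], P[cand[j], , drop = FALSE],
                             method = if (metric == "graph") "graph" else "exact")
      if (d < best) { best <- d; bestj <- cand[j] }
    }
    rows$target[k] <- bestj
    rows$distance[k] <- best
  }
  rows <- rows[!is.na(rows$distance), , drop = FALSE]
  v <- rows$distance
  out <- structure(list(
    per_particle = rows,
    summary = data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
                         sem = stats::sd(v) / sqrt(length(v)))),
    class = "nn_result")
  attr(out, "flagged") <- FALSE
  out
}

#' @export
print.nn_result <- function(x, ...) {
  if (isTRUE(attr(x, "flagged")) || is.null(x$summary)) {
    cat("<nn_result> flagged: fewer than 2 relevant particles\n")
  } else {
    s <- x$summary
    cat(sprintf("<nn_result> n=%d, mean %.2f +/- %.2f nm (SD), SEM %.3f\n",
                s$n, s$mean, s$sd, s$sem))
  }
  invisible(x)
}

is_planar_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  sv <- svd(sweep(v, 2, ctr, "-"), nu = 0, nv = 3)
  sv$d[3] <= tol * max(sv$d[1], 1)
}

#' Boundary polyline of the appressed region
#'
#' Mesh edges separating `appressed` faces from faces with any other label
#' (plus open mesh boundary edges of appressed faces), as a segment set
#' usable by [distance_to_edge()].
#'
#' @param mesh a [tri_mesh].
#' @param labels per-face domain labels.
#' @return list with matrices `A` and `B` (segment endpoints, nm).
#' @export
domain_edge_polyline <- function(mesh, labels) {
  ed <- mesh_edges(mesh)
  l1 <- labels[ed$f1]
  l2 <- ifelse(is.na(ed$f2), NA, labels[ed$f2])
  sel <- (l1 == "appressed" & (is.na(l2) | l2 != "appressed")) |
    (!is.na(l2) & l2 == "appressed" & l1 != "appressed")
  if (!any(sel)) stop("no appressed-region boundary found")
  list(A = mesh$vertices[ed$v1[sel], , drop = FALSE],
       B = mesh$vertices[ed$v2[sel], , drop = FALSE])
}

#' Euclidean distance from particles to a membrane edge
#'
#' 3D chord distance from each particle to the nearest point of the edge
#' polyline, following the convention of measuring edge distances in
#' Euclidean (not geodesic) terms.
#'
#' @param particles a [particle_set()] (or an N x 3 matrix of points).
#' @param edge either a k x 3 matrix (polyline vertices, consecutive rows
#'   joined) or a list with `A`, `B` segment endpoint matrices such as from
#'   [domain_edge_polyline()].
#' @return numeric vector of distances (nm).
#' @export
distance_to_edge <- function(particles, edge) {
  pts <- if (is.matrix(particles)) particles else
    particle_positions(particles)
  seg <- edge_as_segments(edge)
  if (nrow(seg$A) == 0) stop("edge annotation is empty")
  point_segments_distance(pts, seg$A, seg$B)
}

edge_as_segments <- function(edge) {
  if (is.list(edge) && !is.null(edge$A)) {
    list(A = as_point_matrix(edge$A), B = as_point_matrix(edge$B))
  } else {
    m <- as_point_matrix(edge)
    if (nrow(m) < 2) stop("edge polyline needs at least 2 points")
    list(A = m[-nrow(m), , drop = FALSE], B = m[-1, , drop = FALSE])
  }
}

#' Bin triangle areas and particle counts by distance to the region edge
#'
#' Triangles are assigned to half-open bins \[k w, (k+1) w) by the Euclidean
#' distance of their centroid to the edge; particles by their own edge
#' distance. Per-bin concentration is count / area; per-bin mean
#' nearest-neighbor distance is attached when `nn` is supplied.
#'
#' @param particles a [particle_set()].
#' @param mesh the membrane [tri_mesh].
#' @param edge edge annotation (see [distance_to_edge()]).
#' @param bin_width bin width (nm), default 10.
#' @param faces optional face subset defining the analyzed region.
#' @param nn optional `nn_result` whose per-particle distances are averaged
#'   per bin.
#' @return object of class `edge_binning`: data frame with `bin_lo`,
#'   `bin_hi`, `area_um2`, `count`, `concentration_um2`, `mean_nn_nm`.
#' @export
bin_concentrations <- function(particles, mesh, edge, bin_width = 10,
                               faces = seq_len(nrow(mesh$faces)),
                               nn = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  ctr <- face_centroids(mesh)[faces, , drop = FALSE]
  d_face <- distance_to_edge(ctr, edge)
  d_part <- if (nrow(particles) > 0) distance_to_edge(particles, edge)
            else numeric(0)
  n_bin <- max(1L, ceiling((max(c(d_face, d_part), 0) + 1e-9) / bin_width))
  bin_of <- function(d) pmin(floor(d / bin_width), n_bin - 1L) + 1L
  fb <- bin_of(d_face)
  area <- vapply(seq_len(n_bin), function(b)
    sum(mesh$areas[faces][fb == b]), 0)
  cnt <- if (length(d_part)) tabulate(bin_of(d_part), nbins = n_bin)
         else rep(0L, n_bin)
  conc <- ifelse(area > 0, cnt / (area * 1e-6), NA)
  if (any(area == 0 & cnt > 0))
    warning("bin with zero triangle area but nonzero particle count")
  mean_nn <- rep(NA_real_, n_bin)
  if (!is.null(nn) && !is.null(nn$per_particle) && length(d_part)) {
    pb <- bin_of(d_part)[nn$per_particle$source]
    agg <- tapply(nn$per_particle$distance, pb, mean)
    mean_nn[as.integer(names(agg))] <- agg
  }
  structure(data.frame(
    bin_lo = (seq_len(n_bin) - 1L) * bin_width,
    bin_hi = seq_len(n_bin) * bin_width,
    area_um2 = area * 1e-6, count = cnt,
    concentration_um2 = conc, mean_nn_nm = mean_nn),
    class = c("edge_binning", "data.frame"))
}
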