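#' Geodesic distances on a triangle mesh
#'
#' Two backends are provided. `method = "graph"` measures shortest paths on
#' the vertex-edge graph (Dijkstra over mesh edges); this is fast and is
#' always an upper bound on the true polyhedral geodesic. `method = "exact"`
#' refines the graph path: a corridor of faces around the vertex path is
#' augmented with Steiner points on its edges, Dijkstra is re-run on this
#' denser graph (paths may now cross face interiors), and the resulting
#' crossing points are relaxed along their edges until the path length is
#' locally minimal. On planar meshes this converges to the straight-line
#' distance to machine precision; on curved meshes it is a tight upper bound
#' on the exact polyhedral geodesic (within the fixed crossing-edge
#' sequence). The backend used is recorded in the `method` attribute.
#'
#' Endpoints may be arbitrary points near the surface; they are snapped to
#' the nearest mesh face (the snap distance is expected to stay below one
#' face diameter). Targets on a different connected component return `Inf`.
#'
#' @param mesh a [tri_mesh].
#' @param source length-3 world point (nm).
#' @param targets N x 3 matrix of world points (nm).
#' @param method `"exact"` or `"graph"`.
#' @param n_steiner Steiner points per corridor edge for the exact backend.
#' @return numeric vector of distances (nm) with attribute `method`.
#' @export
geodesic_distance <- function(mesh, source, targets,
                              method = c("exact", "graph"),
                              n_steiner = 4L) {
  method <- match.arg(method)
  targets <- as_point_matrix(targets)
  source <- as.numeric(source)
  g <- vertex_graph(mesh)
  snap_s <- snap_to_mesh(mesh, matrix(source, 1, 3))
  snap_t <- snap_to_mesh(mesh, targets)
  vs <- snap_s$vertex[1]
  vt <- snap_t$vertex
  if (method == "graph") {
    d <- igraph::distances(g, v = vs, to = unique(vt))[1, ]
    out <- d[match(vt, unique(vt))]
    attr(out, "method") <- "graph"
    names(out) <- NULL
    return(out)
  }
  vf <- vertex_faces(mesh)
  out <- numeric(nrow(targets))
  ds <- igraph::distances(g, v = vs)[1, ]
  max_edge <- max(igraph::E(g)$weight)
  for (i in seq_len(nrow(targets))) {
    if (!is.finite(ds[vt[i]])) {  # disconnected
      out[i] <- Inf
      next
    }
    dt <- igraph::distances(g, v = vt[i])[1, ]
    # two-sided corridor: every vertex on a near-shortest graph path
    corridor <- which(ds + dt <= ds[vt[i]] * 1.05 + 2 * max_edge)
    out[i] <- refine_geodesic(mesh, vf,
                              src_pt = snap_s$point[1, ],
                              src_face = snap_s$face[1],
                              dst_pt = snap_t$point[i, ],
                              dst_face = snap_t$face[i],
                              corridor_verts = corridor,
                              n_steiner = n_steiner)
  }
  attr(out, "method") <- "exact"
  out
}

# Snap points to the mesh: nearest vertex, then best projection onto an
# incident face. Returns face id, snapped point, and the nearest vertex.
snap_to_mesh <- function(mesh, pts) {
  pts <- as_point_matrix(pts)
  v <- mesh$vertices
  vf <- vertex_faces(mesh)
  n <- nrow(pts)
  face <- integer(n); vert <- integer(n)
  snapped <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    d2 <- (v[, 1] - p[1])^2 + (v[, 2] - p[2])^2 + (v[, 3] - p[3])^2
    nv <- which.min(d2)
    vert[i] <- nv
    cand <- vf[[as.character(nv)]]
    best <- Inf; bf <- cand[1]; bp <- v[nv, ]
    for (f in cand) {
      tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
      pr <- project_point_triangle(p, tri)
      dd <- sum((pr - p)^2)
      if (dd < best) { best <- dd; bf <- f; bp <- pr }
    }
    face[i] <- bf
    snapped[i, ] <- bp
  }
  list(face = face, point = snapped, vertex = vert)
}

# closest point on a triangle (barycentric clamping)
project_point_triangle <- function(p, tri) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  den <- va + vb + vc
  a + ab * vb / den + ac * vc / den
}

# Corridor Steiner refinement of one source-target geodesic query.
refine_geodesic <- function(mesh, vf, src_pt, src_face, dst_pt, dst_face,
                            corridor_verts, n_steiner = 4L) {
  if (src_face == dst_face)
    return(sqrt(sum((src_pt - dst_pt)^2)))
  # faces incident to corridor vertices, dilated one ring, plus endpoints
  fset <- unique(unlist(vf[as.character(corridor_verts)], use.names = FALSE))
  verts <- unique(as.vector(mesh$faces[fset, , drop = FALSE]))
  fset <- unique(c(unlist(vf[as.character(verts)], use.names = FALSE),
                   src_face, dst_face))
  faces <- mesh$faces[fset, , drop = FALSE]
  # planar shortcut: if the corridor is coplanar and the straight segment
  # from source to target stays inside it, the chord is the exact geodesic
  pl <- planar_chord(mesh, faces, src_pt, dst_pt)
  if (!is.na(pl)) return(pl)
  # node table: id -> position + supporting edge (v1,v2,t) for relaxation
  vids <- sort(unique(as.vector(faces)))
  nvert <- length(vids)
  vmap <- integer(max(vids)); vmap[vids] <- seq_len(nvert)
  pos <- mesh$vertices[vids, , drop = FALSE]
  sup_a <- vids; sup_b <- vids   # vertex nodes: degenerate support
  # unique corridor edges
  eraw <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ekey <- paste(pmin(eraw[, 1], eraw[, 2]), pmax(eraw[, 1], eraw[, 2]))
  ufirst <- !duplicated(ekey)
  ue <- cbind(pmin(eraw[ufirst, 1], eraw[ufirst, 2]),
              pmax(eraw[ufirst, 1], eraw[ufirst, 2]))
  ekey_u <- ekey[ufirst]
  k <- max(0L, as.integer(n_steiner))
  n_edge_nodes <- k * nrow(ue)
  if (k > 0) {
    tfrac <- (seq_len(k)) / (k + 1)
    p1 <- mesh$vertices[ue[, 1], , drop = FALSE]
    p2 <- mesh$vertices[ue[, 2], , drop = FALSE]
    spos <- do.call(rbind, lapply(tfrac, function(tt) p1 + tt * (p2 - p1)))
    pos <- rbind(pos, spos)
    sup_a <- c(sup_a, rep(ue[, 1], times = k))
    sup_b <- c(sup_b, rep(ue[, 2], times = k))
  }
  # endpoint nodes
  pos <- rbind(pos, src_pt, dst_pt)
  sup_a <- c(sup_a, 0L, 0L)  # fixed points
  sup_b <- c(sup_b, 0L, 0L)
  id_src <- nrow(pos) - 1L
  id_dst <- nrow(pos)
  # per-face node lists: 3 vertices + Steiner nodes of its 3 edges
  edge_node_ids <- function(eidx) {
    if (k == 0L || length(eidx) == 0L) return(integer(0))
    as.vector(vapply(seq_len(k) - 1L,
                     function(j) nvert + j * nrow(ue) + eidx,
                     integer(length(eidx))))
  }
  eidx_of <- function(a, b) match(paste(pmin(a, b), pmax(a, b)), ekey_u)
  from <- integer(0); to <- integer(0)
  for (fi in seq_len(nrow(faces))) {
    tri <- faces[fi, ]
    nodes <- c(vmap[tri],
               edge_node_ids(eidx_of(tri[c(1, 2, 3)], tri[c(2, 3, 1)])))
    if (fset[fi] == src_face) nodes <- c(nodes, id_src)
    if (fset[fi] == dst_face) nodes <- c(nodes, id_dst)
    pr <- t(utils::combn(nodes, 2L))
    from <- c(from, pr[, 1]); to <- c(to, pr[, 2])
  }
  w <- sqrt(rowSums((pos[from, , drop = FALSE] - pos[to, , drop = FALSE])^2))
  gg <- igraph::make_graph(rbind(from, to), n = nrow(pos), directed = FALSE)
  igraph::E(gg)$weight <- w
  pth <- igraph::shortest_paths(gg, from = id_src, to = id_dst,
                                output = "vpath")$vpath[[1]]
  pth <- as.integer(pth)
  if (length(pth) < 2L) return(Inf)
  P <- pos[pth, , drop = FALSE]
  sa <- sup_a[pth]; sb <- sup_b[pth]
  end_faces <- c(src_face, dst_face)
  len <- Inf
  # alternate sleeve conversion (release vertex pass-throughs) and edge
  # relaxation until the length stops improving
  for (round in 1:6) {
    sl <- sleeve_pass(mesh, vf, P, sa, sb, end_faces)
    rx <- relax_chain(sl$P, sl$sa, sl$sb, mesh$vertices)
    # clamp: nodes relaxed onto a supporting vertex become vertex nodes
    cl <- clamp_chain(rx$P, sl$sa, sl$sb, mesh$vertices)
    improved <- len - rx$len > 1e-9 * max(1, rx$len)
    P <- cl$P; sa <- cl$sa; sb <- cl$sb; len <- rx$len
    if (!improved || !cl$any_clamped) break
  }
  len
}

# After relaxation, movable nodes that slid to the end of their supporting
# edge are converted to vertex nodes so the next sleeve pass can release
# them around the vertex.
clamp_chain <- function(P, sa, sb, verts, eps = 1e-7) {
  any_cl <- FALSE
  for (i in seq_along(sa)) {
    if (sa[i] > 0L && sb[i] > 0L && sa[i] != sb[i]) {
      e0 <- verts[sa[i], ]; e1 <- verts[sb[i], ]
      L <- sqrt(sum((e1 - e0)^2))
      t <- sum((P[i, ] - e0) * (e1 - e0)) / (L * L)
      if (t < eps) {
        P[i, ] <- e0; sb[i] <- sa[i]; any_cl <- TRUE
      } else if (t > 1 - eps) {
        P[i, ] <- e1; sa[i] <- sb[i]; any_cl <- TRUE
      }
    }
  }
  list(P = P, sa = sa, sb = sb, any_clamped = any_cl)
}

# Convert a path into a relaxable "sleeve": interior nodes that sit exactly
# on mesh vertices are immovable for edge relaxation, so each is either
# dropped (when its neighbors already share a face) or replaced by movable
# crossing nodes on the interior edges of the face fan around that vertex
# (the cheaper of the fan arcs is kept).
sleeve_pass <- function(mesh, vf, P, sa, sb, end_faces) {
  m <- nrow(P)
  faces_of <- function(i) {
    if (sa[i] == 0L) {
      end_faces[if (i == 1L) 1L else 2L]
    } else if (sa[i] == sb[i]) {
      vf[[as.character(sa[i])]]
    } else {
      intersect(vf[[as.character(sa[i])]], vf[[as.character(sb[i])]])
    }
  }
  out_P <- list(P[1, ]); out_sa <- 0L; out_sb <- 0L
  last_faces <- faces_of(1L)
  push <- function(p, a, b, fcs) {
    out_P[[length(out_P) + 1L]] <<- p
    out_sa <<- c(out_sa, a); out_sb <<- c(out_sb, b)
    last_faces <<- fcs
  }
  for (i in seq2(2L, m - 1L)) {
    next_faces <- faces_of(i + 1L)
    # drop any node whose neighbors already share a face: the straight
    # segment inside that face is on-surface and never longer
    if (length(intersect(last_faces, next_faces)) > 0L) next
    if (sa[i] == 0L || sa[i] != sb[i]) {  # endpoint or edge-interior node
      push(P[i, ], sa[i], sb[i], faces_of(i))
      next
    }
    v <- sa[i]
    fan <- vertex_fan(mesh, v, vf)
    Fp <- intersect(last_faces, fan$faces)
    Fn <- intersect(next_faces, fan$faces)
    if (length(Fp) == 0L || length(Fn) == 0L) {  # fallback: keep pinned
      push(P[i, ], v, v, vf[[as.character(v)]])
      next
    }
    best <- NULL; best_len <- Inf
    for (fp in Fp) for (fn in Fn) for (dir in c(1L, -1L)) {
      arc <- fan_arc_edges(fan, fp, fn, dir, v, mesh)
      if (is.null(arc)) next
      if (length(arc$other) == 0L) { cand_len <- 0; cand <- arc; }
      # local relax of the inserted nodes between fixed neighbors
      np <- length(arc$other)
      Pl <- rbind(unlist(out_P[length(out_P)]),
                  if (np) (mesh$vertices[rep(v, np), , drop = FALSE] +
                             mesh$vertices[arc$other, , drop = FALSE]) / 2,
                  P[i + 1L, ])
      ln <- relax_path_length(Pl, c(0L, rep(v, np), 0L),
                              c(0L, arc$other, 0L), mesh$vertices,
                              max_sweeps = 50)
      if (ln < best_len) { best_len <- ln; best <- arc }
    }
    if (is.null(best)) {
      push(P[i, ], v, v, vf[[as.character(v)]])
    } else if (length(best$other)) {
      for (x in best$other)
        push((mesh$vertices[v, ] + mesh$vertices[x, ]) / 2, v, x,
             intersect(vf[[as.character(v)]], vf[[as.character(x)]]))
    }
    # if arc has no interior edges, prev and next were fan-adjacent: drop v
  }
  push(P[m, ], 0L, 0L, faces_of(m))
  list(P = do.call(rbind, out_P), sa = out_sa, sb = out_sb)
}

# ordered (cyclic if closed) fan of faces around vertex v
vertex_fan <- function(mesh, v, vf) {
  fcs <- vf[[as.character(v)]]
  if (length(fcs) <= 1L) return(list(faces = fcs, closed = FALSE))
  # the two vertices each fan face pairs with v
  others <- lapply(fcs, function(f) setdiff(mesh$faces[f, ], v))
  # walk: adjacency between fan faces sharing an edge (v, x)
  nb <- lapply(seq_along(fcs), function(a) {
    which(vapply(seq_along(fcs), function(b)
      b != a && length(intersect(others[[a]], others[[b]])) > 0L,
      logical(1)))
  })
  deg1 <- which(vapply(nb, length, 0L) < 2L)
  closed <- length(deg1) == 0L
  start <- if (closed) 1L else deg1[1]
  ord <- start; prev <- 0L; cur <- start
  repeat {
    nxt <- setdiff(nb[[cur]], prev)
    if (length(nxt) == 0L) break
    nxt <- nxt[1]
    if (nxt == start) break
    ord <- c(ord, nxt); prev <- cur; cur <- nxt
    if (length(ord) >= length(fcs)) break
  }
  list(faces = fcs[ord], closed = closed,
       others = others[ord])
}

# interior fan edges (as the non-v vertex of each crossed edge) walking from
# face fp to face fn in direction dir; NULL if the walk is impossible
fan_arc_edges <- function(fan, fp, fn, dir, v, mesh) {
  n <- length(fan$faces)
  ip <- match(fp, fan$faces); im <- match(fn, fan$faces)
  if (is.na(ip) || is.na(im)) return(NULL)
  idx <- ip; seqf <- ip
  while (idx != im) {
    idx <- idx + dir
    if (idx < 1L || idx > n) {
      if (!fan$closed) return(NULL)
      idx <- ((idx - 1L) %% n) + 1L
    }
    seqf <- c(seqf, idx)
    if (length(seqf) > n) return(NULL)
  }
  if (length(seqf) <= 1L) return(list(other = integer(0)))
  other <- integer(0)
  for (j in seq_len(length(seqf) - 1L)) {
    shared <- intersect(fan$others[[seqf[j]]], fan$others[[seqf[j + 1L]]])
    if (length(shared) == 0L) return(NULL)
    other <- c(other, shared[1])
  }
  list(other = other)
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

# Exact chord distance when a face set is coplanar and contains the segment;
# NA when the shortcut does not apply.
planar_chord <- function(mesh, faces, src_pt, dst_pt) {
  vid <- unique(as.vector(faces))
  V <- mesh$vertices[vid, , drop = FALSE]
  ctr <- colMeans(V)
  Vc <- sweep(V, 2, ctr, "-")
  sv <- svd(Vc, nu = 0, nv = 3)
  diam <- max(abs(Vc))
  if (diam <= 0) return(NA_real_)
  if (sv$d[3] > 1e-7 * diam) return(NA_real_)      # not coplanar
  n <- sv$v[, 3]
  if (abs(sum((src_pt - ctr) * n)) > 1e-6 * max(1, diam) ||
      abs(sum((dst_pt - ctr) * n)) > 1e-6 * max(1, diam))
    return(NA_real_)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
  to2d <- function(p) c(sum((p - ctr) * e1), sum((p - ctr) * e2))
  A <- to2d(src_pt); B <- to2d(dst_pt)
  P1 <- cbind(Vc %*% e1, Vc %*% e2)
  lk <- integer(max(vid)); lk[vid] <- seq_along(vid)
  t1 <- P1[lk[faces[, 1]], , drop = FALSE]
  t2 <- P1[lk[faces[, 2]], , drop = FALSE]
  t3 <- P1[lk[faces[, 3]], , drop = FALSE]
  ts <- seq(0, 1, length.out = 256)
  qx <- A[1] + ts * (B[1] - A[1]); qy <- A[2] + ts * (B[2] - A[2])
  tol <- 1e-9 * max(1, diam)
  sgn <- function(ax, ay, bx, by, px, py)
    (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  covered <- rep(FALSE, length(ts))
  for (f in seq_len(nrow(faces))) {
    d1 <- sgn(t1[f, 1], t1[f, 2], t2[f, 1], t2[f, 2], qx, qy)
    d2 <- sgn(t2[f, 1], t2[f, 2], t3[f, 1], t3[f, 2], qx, qy)
    d3 <- sgn(t3[f, 1], t3[f, 2], t1[f, 1], t1[f, 2], qx, qy)
    inside <- (d1 >= -tol & d2 >= -tol & d3 >= -tol) |
      (d1 <= tol & d2 <= tol & d3 <= tol)
    covered <- covered | inside
    if (all(covered)) break
  }
  if (all(covered)) sqrt(sum((dst_pt - src_pt)^2)) else NA_real_
}

# Iterative relaxation of interior path nodes along their supporting mesh
# edges (coordinate descent on the crossing parameter; golden-section on a
# convex 1D objective). Fixed points (support 0) and mesh-vertex nodes do
# not move. Returns the relaxed length and node positions.
relax_chain <- function(P, sup_a, sup_b, verts,
                        max_sweeps = 1000, tol = 1e-13) {
  .relax_chain_cpp(P, as.integer(sup_a), as.integer(sup_b), verts,
                   as.integer(max_sweeps), tol)
}

relax_path_length <- function(P, sup_a, sup_b, verts, max_sweeps = 400,
                              tol = 1e-12) {
  relax_chain(P, sup_a, sup_b, verts, max_sweeps, tol)$len
}

#' Faces within a geodesic radius of a query face
#'
#' Distances between faces are measured on the face-adjacency graph (faces
#' sharing an edge, weighted by centroid-to-centroid distance), the standard
#' discrete surrogate for centroid geodesics. `radius = 0` returns only the
#' query face.
#'
#' @param mesh a [tri_mesh].
#' @param face face index.
#' @param radius geodesic radius (nm).
#' @return sorted integer vector of face indices (always includes `face`).
#' @export
geodesic_neighborhood <- function(mesh, face, radius) {
  if (radius < 0) stop("radius must be >= 0")
  adj <- face_adjacency(mesh)
  ctr <- face_centroids(mesh)
  w <- sqrt(rowSums((ctr[adj[, 1], , drop = FALSE] -
                       ctr[adj[, 2], , drop = FALSE])^2))
  unique(.faces_within_radius(as.integer(face), nrow(mesh$faces),
                              adj, w, radius))
}
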