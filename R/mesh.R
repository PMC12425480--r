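#' Triangle mesh in physical coordinates
#'
#' The central geometric container: vertices in world nanometers, triangular
#' faces (1-based vertex indices), with per-face unit normals and areas
#' computed on construction. Optional per-face labels travel with the mesh.
#'
#' @param vertices N x 3 numeric matrix (nm).
#' @param faces M x 3 integer matrix of vertex indices (1-based).
#' @param labels optional per-face vector (length M).
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `normals` (M x 3 unit vectors), `areas` (nm^2), and `labels`.
#' @export
tri_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as_point_matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must be M x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("faces index vertices outside 1..N")
  if (!is.null(labels) && length(labels) != nrow(faces))
    stop("labels must have one entry per face")
  m <- structure(list(vertices = vertices, faces = faces, labels = labels),
                 class = "tri_mesh")
  geom <- face_geometry(m)
  m$normals <- geom$normals
  m$areas <- geom$areas
  m
}

face_geometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L)
    return(list(normals = matrix(0, 0, 3), areas = numeric(0)))
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  normals <- cr / ifelse(nrm > 0, nrm, 1)
  list(normals = normals, areas = nrm / 2)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces, area %.4g nm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  if (!is.null(x$labels))
    cat("  face labels:", paste(utils::head(unique(x$labels), 6), collapse = ", "), "\n")
  invisible(x)
}

#' Total mesh surface area (nm^2)
#' @param mesh a [tri_mesh].
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Face centroids
#' @param mesh a [tri_mesh].
#' @return M x 3 matrix (nm).
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

# Undirected edge table: one row per unique edge with the 1 or 2 adjacent
# faces. Cached computations share this through mesh_edges().
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep.int(seq_len(nrow(f)), 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  grp <- match(key, unique(key))
  ord <- order(grp)
  grp_o <- grp[ord]; fid_o <- fid[ord]; e_o <- e[ord, , drop = FALSE]
  first <- !duplicated(grp_o)
  n_edge <- sum(first)
  f1 <- fid_o[first]
  f2 <- rep(NA_integer_, n_edge)
  dup_idx <- which(!first)
  f2[grp_o[dup_idx]] <- fid_o[dup_idx]
  list(v1 = pmin(e_o[first, 1], e_o[first, 2]),
       v2 = pmax(e_o[first, 1], e_o[first, 2]),
       f1 = f1, f2 = f2)
}

#' Face adjacency (faces sharing an edge)
#' @param mesh a [tri_mesh].
#' @return two-column integer matrix of adjacent face pairs.
#' @export
face_adjacency <- function(mesh) {
  ed <- mesh_edges(mesh)
  keep <- !is.na(ed$f2)
  cbind(ed$f1[keep], ed$f2[keep])
}

#' Faces with at least one open-boundary edge
#' @param mesh a [tri_mesh].
#' @return logical vector over faces.
#' @export
boundary_faces <- function(mesh) {
  ed <- mesh_edges(mesh)
  open_f <- ed$f1[is.na(ed$f2)]
  out <- rep(FALSE, nrow(mesh$faces))
  out[open_f] <- TRUE
  out
}

#' Open boundary edges of a mesh
#' @param mesh a [tri_mesh].
#' @return two-column matrix of vertex index pairs forming boundary edges.
#' @export
boundary_edges <- function(mesh) {
  ed <- mesh_edges(mesh)
  keep <- is.na(ed$f2)
  cbind(ed$v1[keep], ed$v2[keep])
}

# igraph over mesh vertices, edge weights = Euclidean edge lengths (nm)
vertex_graph <- function(mesh) {
  ed <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[ed$v1, , drop = FALSE] -
                       mesh$vertices[ed$v2, , drop = FALSE])^2))
  g <- igraph::make_graph(rbind(ed$v1, ed$v2), n = nrow(mesh$vertices),
                          directed = FALSE)
  igraph::E(g)$weight <- w
  g
}

# Vertex -> incident faces (list), and face k-ring around a face
vertex_faces <- function(mesh) {
  f <- mesh$faces
  split(rep.int(seq_len(nrow(f)), 3L), as.vector(f))
}

face_ring <- function(mesh, face, k = 2L, vf = NULL) {
  if (is.null(vf)) vf <- vertex_faces(mesh)
  cur <- face
  for (i in seq_len(k)) {
    verts <- unique(as.vector(mesh$faces[cur, , drop = FALSE]))
    cur <- unique(unlist(vf[as.character(verts)], use.names = FALSE))
  }
  sort(cur)
}

#' Rigid transform of a mesh
#'
#' @param mesh a [tri_mesh].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (nm).
#' @return transformed [tri_mesh].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_mesh(v, mesh$faces, labels = mesh$labels)
}

#' Midpoint 1-to-4 subdivision
#'
#' Each triangle is split into four by inserting edge midpoints. Used in
#' convergence tests of the geodesic backends.
#' @param mesh a [tri_mesh].
#' @return subdivided [tri_mesh].
#' @export
subdivide_mesh <- function(mesh) {
  ed <- mesh_edges(mesh)
  n_v <- nrow(mesh$vertices)
  mid <- (mesh$vertices[ed$v1, , drop = FALSE] +
            mesh$vertices[ed$v2, , drop = FALSE]) / 2
  ekey <- paste(ed$v1, ed$v2)
  midx <- function(a, b) n_v + match(paste(pmin(a, b), pmax(a, b)), ekey)
  f <- mesh$faces
  m12 <- midx(f[, 1], f[, 2]); m23 <- midx(f[, 2], f[, 3]); m31 <- midx(f[, 3], f[, 1])
  nf <- rbind(cbind(f[, 1], m12, m31),
              cbind(f[, 2], m23, m12),
              cbind(f[, 3], m31, m23),
              cbind(m12, m23, m31))
  tri_mesh(rbind(mesh$vertices, mid), nf)
}

#' Connected components of a mesh (by shared vertices)
#' @param mesh a [tri_mesh].
#' @return integer vector: component id per face.
#' @export
mesh_components <- function(mesh) {
  g <- vertex_graph(mesh)
  comp <- igraph::components(g)$membership
  comp[mesh$faces[, 1]]
}

#' Concatenate meshes into one, tracking membrane ids
#'
#' @param meshes list of [tri_mesh].
#' @return a [tri_mesh] whose `labels` keep any per-mesh labels and with an
#'   attribute `membrane` giving, per face, the index of the source mesh.
#' @export
merge_meshes <- function(meshes) {
  off <- 0L
  vs <- list(); fs <- list(); memb <- list(); labs <- list()
  has_labs <- all(vapply(meshes, function(m) !is.null(m$labels), logical(1)))
  for (i in seq_along(meshes)) {
    m <- meshes[[i]]
    vs[[i]] <- m$vertices
    fs[[i]] <- m$faces + off
    memb[[i]] <- rep.int(i, nrow(m$faces))
    if (has_labs) labs[[i]] <- m$labels
    off <- off + nrow(m$vertices)
  }
  out <- tri_mesh(do.call(rbind, vs), do.call(rbind, fs),
                  labels = if (has_labs) unlist(labs) else NULL)
  attr(out, "membrane") <- unlist(memb)
  out
}
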