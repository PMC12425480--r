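# shared fixtures built in code at test time

# triangular lattice of points with given spacing inside a centered square
lattice_particles <- function(spacing = 21, half = 130) {
  pts <- list()
  for (r in 0:24) for (cl in 0:24) {
    x <- cl * spacing + (r %% 2) * spacing / 2 - half - 10
    y <- r * spacing * sqrt(3) / 2 - half - 10
    if (abs(x) < half && abs(y) < half)
      pts[[length(pts) + 1L]] <- c(x, y)
  }
  P <- do.call(rbind, pts)
  particle_set(data.frame(x = P[, 1], y = P[, 2], z = 0))
}

# fraction of non-excluded area correctly labeled against phantom truth
domain_accuracy <- function(classified, truth) {
  ok <- 0; tot <- 0
  for (i in seq_along(classified$labels)) {
    l <- classified$labels[[i]]
    g <- truth$meshes[[i]]$labels
    a <- truth$meshes[[i]]$areas
    keep <- l != "excluded"
    ok <- ok + sum(a[keep & l == g])
    tot <- tot + sum(a[keep])
  }
  ok / tot
}

# independent raster oracle for polygon areas: point-in-polygon tests with
# mgcv::in.out on a 0.5 nm grid (distinct code path from the package's
# clipping and scanline rasterizer)
oracle_union_area <- function(polys, px = 0.5, pad = 2) {
  allp <- do.call(rbind, polys)
  gx <- seq(min(allp[, 1]) - pad, max(allp[, 1]) + pad, by = px)
  gy <- seq(min(allp[, 2]) - pad, max(allp[, 2]) + pad, by = px)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- rep(FALSE, nrow(G))
  for (p in polys)
    inside <- inside | mgcv::in.out(rbind(p, p[1, ]), G)
  sum(inside) * px^2
}

oracle_intersection_area <- function(p1, p2, px = 0.5, pad = 2) {
  allp <- rbind(p1, p2)
  gx <- seq(min(allp[, 1]) - pad, max(allp[, 1]) + pad, by = px)
  gy <- seq(min(allp[, 2]) - pad, max(allp[, 2]) + pad, by = px)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  sum(mgcv::in.out(rbind(p1, p1[1, ]), G) &
        mgcv::in.out(rbind(p2, p2[1, ]), G)) * px^2
}

# tiny synthetic atomic-coordinate file (PDB format) for footprint tests:
# an elliptical slab of pseudo-atoms; labelled synthetic, not a real complex
write_synthetic_pdb <- function(path, a = 8, b = 4, n = 400, seed = 1) {
  set.seed(seed)
  xy <- matrix(0, 0, 2)
  while (nrow(xy) < n) {
    p <- cbind(runif(n, -a, a), runif(n, -b, b))
    keep <- (p[, 1] / a)^2 + (p[, 2] / b)^2 <= 1
    xy <- rbind(xy, p[keep, , drop = FALSE])
  }
  xy <- xy[seq_len(n), ] * 10  # nm -> A
  z <- runif(n, -15, 15)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), xy[, 1], xy[, 2], z)
  writeLines(c(lines, "END"), path)
  path
}
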