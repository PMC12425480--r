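test_that("triangular lattices have exact nearest-neighbor distances", {
  mesh <- flat_square_mesh(300, 300, spacing = 10)
  ps <- lattice_particles(spacing = 21)
  nn <- nn_distances(ps, mesh, include_clipped_sources = TRUE)
  expect_equal(unique(round(nn$per_particle$distance, 9)), 21)
  # two particles 50 nm apart: both NN = 50 by symmetry
  ps2 <- particle_set(data.frame(x = c(0, 50), y = 0, z = 0))
  nn2 <- nn_distances(ps2, mesh, include_clipped_sources = TRUE)
  expect_equal(nn2$per_particle$distance, c(50, 50))
})

test_that("flat-membrane NN equals the planar brute-force oracle exactly", {
  mesh <- flat_square_mesh(500, 500, spacing = 10)
  ps <- sample_particles_hardcore(mesh,
                                  particle_model("PSII", min_separation = 13),
                                  seed = 4)
  nn <- nn_distances(ps, mesh, include_clipped_sources = TRUE)
  P <- cbind(ps$x, ps$y, ps$z)
  D <- as.matrix(dist(P)); diag(D) <- Inf
  oracle <- apply(D, 1, min)
  expect_equal(nn$per_particle$distance, unname(oracle), tolerance = 1e-12)
})

test_that("hard-core NN statistics match the brute-force oracle across seeds", {
  mesh <- flat_square_mesh(600, 600, spacing = 10)
  model <- particle_model("PSII", min_separation = 13)
  for (s in 1:5) {
    ps <- sample_particles_hardcore(mesh, model, seed = s)
    nn <- nn_distances(ps, mesh, include_clipped_sources = TRUE)
    P <- cbind(ps$x, ps$y, ps$z)
    D <- as.matrix(dist(P)); diag(D) <- Inf
    expect_equal(nn$summary$mean, mean(apply(D, 1, min)), tolerance = 1e-9)
    expect_gte(min(nn$per_particle$distance), 13)
  }
})

test_that("geodesic NN upper-bounds chord NN on curved membranes", {
  cy <- cylinder_mesh(30, 100, n_around = 40, n_along = 16)
  ps <- sample_particles_hardcore(cy, particle_model("PSII", density = 900,
                                                     min_separation = 10),
                                  seed = 6)
  nng <- nn_distances(ps, cy, metric = "geodesic",
                      include_clipped_sources = TRUE)
  nnc <- nn_distances(ps, cy, metric = "chord",
                      include_clipped_sources = TRUE)
  expect_true(all(nng$per_particle$distance >=
                    nnc$per_particle$distance - 1e-9))
})

test_that("too few particles yield a flagged empty result", {
  mesh <- flat_square_mesh(100, 100, spacing = 10)
  expect_true(attr(nn_distances(particle_set(), mesh), "flagged"))
  one <- particle_set(data.frame(x = 0, y = 0, z = 0))
  expect_true(attr(nn_distances(one, mesh), "flagged"))
})

test_that("edge distances follow planar geometry and a resampling oracle", {
  # straight edge at x = 0: particle 35 nm in
  edge <- rbind(c(0, -100, 0), c(0, 100, 0))
  ps <- particle_set(data.frame(x = c(0, 35), y = c(10, -20), z = 0))
  d <- distance_to_edge(ps, edge)
  expect_equal(d, c(0, 35))
  # curved edge: compare with brute-force min over a dense resampling
  th <- seq(0, pi, length.out = 41)
  curve <- cbind(50 * cos(th), 50 * sin(th), 0)
  pts <- particle_set(data.frame(x = c(10, 80, 0), y = c(10, 30, 60), z = 0))
  d2 <- distance_to_edge(pts, curve)
  thd <- seq(0, pi, length.out = 40001)
  dense <- cbind(50 * cos(thd), 50 * sin(thd), 0)
  for (i in 1:3) {
    o <- min(sqrt((dense[, 1] - pts$x[i])^2 + (dense[, 2] - pts$y[i])^2))
    expect_equal(d2[i], o, tolerance = 0.5)
  }
  expect_error(distance_to_edge(ps, list(A = matrix(0, 0, 3),
                                         B = matrix(0, 0, 3))), "empty")
})

test_that("edge binning conserves counts and areas exactly", {
  mesh <- flat_square_mesh(200, 200, spacing = 5)
  edge <- rbind(c(-100, -100, 0), c(-100, 100, 0))  # left side
  set.seed(9)
  ps <- sample_particles_hardcore(mesh, particle_model("PSII", density = 500,
                                                       min_separation = 0),
                                  seed = 9)
  eb <- bin_concentrations(ps, mesh, edge, bin_width = 10)
  expect_identical(sum(eb$count), nrow(ps))
  expect_equal(sum(eb$area_um2) * 1e6, mesh_area(mesh), tolerance = 1e-9)
})

test_that("uniform patterns give flat per-bin concentrations within Poisson bounds", {
  mesh <- flat_square_mesh(400, 400, spacing = 8)
  edge <- rbind(c(-200, -200, 0), c(-200, 200, 0))
  lam <- 1415  # per um^2
  ps <- sample_particles_hardcore(mesh, particle_model("PSII", density = lam,
                                                       min_separation = 0),
                                  seed = 12)
  eb <- bin_concentrations(ps, mesh, edge, bin_width = 10)
  full <- eb$area_um2 > 0.9 * max(eb$area_um2)  # interior bins
  expect_true(all(abs(eb$count[full] - lam * eb$area_um2[full]) <=
                    3 * sqrt(lam * eb$area_um2[full])))
})

test_that("degenerate binning cases behave as documented", {
  mesh <- flat_square_mesh(40, 40, spacing = 5)
  edge <- rbind(c(-15, -20, 0), c(-15, 20, 0))
  # all particles at edge distance 5: every count in bin [0, 10)
  ps <- particle_set(data.frame(x = -10, y = c(-5, 0, 5), z = 0))
  eb <- bin_concentrations(ps, mesh, edge, bin_width = 10)
  expect_identical(eb$count[1], 3L)
  expect_identical(sum(eb$count[-1]), 0L)
  # empty particle set: concentrations zero, areas still reported
  eb0 <- bin_concentrations(particle_set(), mesh, edge, bin_width = 10)
  expect_true(all(eb0$count == 0L))
  expect_gt(sum(eb0$area_um2), 0)
})

test_that("the appressed-region boundary is extracted as a usable polyline", {
  ph <- make_granum_phantom(geometry_params(granum_radius = 40,
                                            mesh_spacing = 5),
                            density = FALSE)
  cd <- classify_domains(ph$truth$meshes, curvature_cutoff = Inf)
  edge <- domain_edge_polyline(ph$truth$meshes[[2]], cd$labels[[2]])
  expect_gt(nrow(edge$A), 10)
  # boundary segments hug the disc rim
  r <- sqrt((edge$A[, 1] - ph$truth$center[1])^2 +
              (edge$A[, 2] - ph$truth$center[2])^2)
  expect_true(all(abs(r - 40) < 12))
})
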