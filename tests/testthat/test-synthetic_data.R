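test_that("phantom stack height follows the layered construction", {
  p <- geometry_params()  # 5.1 / 3.2 / 10.8 defaults
  lay <- granametrics:::granum_layout(p)
  expect_equal(lay$stack_height, 3 * 21.0 + 2 * 3.2, tolerance = 1e-9)
  # voxel mask extent agrees within one voxel
  ph <- make_granum_phantom(p, density = FALSE)
  zocc <- which(apply(ph$mask$values, 3, sum) > 0)
  extent <- (max(zocc) - min(zocc) + 1) * p$voxel_size
  expect_lt(abs(extent - lay$stack_height), p$voxel_size)
})

test_that("ground-truth appressed area equals 2(n-1) disc areas", {
  for (n in c(2, 4)) {
    ph <- make_granum_phantom(geometry_params(n_thylakoids = n),
                              density = FALSE)
    ta <- phantom_truth_areas(ph$truth)
    disc <- mesh_area(ph$truth$meshes[[2]])  # interior membrane = pure disc
    expect_equal(unname(ta["appressed"]), 2 * (n - 1) * disc,
                 tolerance = 1e-12)
  }
  # a single thylakoid has no stacking partner
  ph1 <- make_granum_phantom(geometry_params(n_thylakoids = 1,
                                             lamella_length = 0),
                             density = FALSE)
  expect_identical(unname(phantom_truth_areas(ph1$truth)["appressed"]), 0)
})

test_that("noiseless density is mirror-symmetric through the stack mid-plane", {
  ph <- make_granum_phantom(geometry_params(noise_sigma = 0))
  v <- ph$density$values
  expect_lt(max(abs(v - v[, , dim(v)[3]:1])), 1e-12)
})

test_that("mask volume matches the analytic slab volume within 2 percent", {
  p <- geometry_params(granum_radius = 30, lamella_length = 0,
                       voxel_size = 0.5, volume_shape = c(140, 140, 170),
                       noise_sigma = 0)
  ph <- make_granum_phantom(p, density = FALSE)
  vol_mask <- sum(ph$mask$values) * 0.5^3
  vol_true <- 6 * pi * 30^2 * 5.1  # 6 membranes x disc x thickness
  expect_lt(abs(vol_mask / vol_true - 1), 0.02)
})

test_that("geometry that does not fit the volume names the offending dimension", {
  expect_error(make_granum_phantom(geometry_params(granum_radius = 200)),
               "x extent")
  expect_error(
    make_granum_phantom(geometry_params(n_thylakoids = 8,
                                        volume_shape = c(144, 112, 60))),
    "z extent")
})

test_that("leaflet rendering places outer half-max crossings at the membrane boundary", {
  t <- 5.1
  z <- seq(-6, 6, by = 0.001)
  f <- granametrics:::bilayer_profile(z, t)
  # two peaks separated by less than the membrane thickness
  pk <- z[which(diff(sign(diff(f))) == -2) + 1]
  expect_identical(length(pk), 2L)
  expect_lt(diff(pk), t)
  # outer half-max crossings exactly t apart
  right <- z[z > pk[2]]
  cross_r <- right[which(f[z > pk[2]] <= 0.5)[1]]
  expect_equal(cross_r, t / 2, tolerance = 2e-3)
  expect_equal(max(f), 1, tolerance = 1e-9)
})

test_that("hard-core sampling enforces separation and target count", {
  mesh <- flat_square_mesh(1000, 1000, spacing = 10)
  model <- particle_model("PSII", min_separation = 13)  # 1415 / um^2
  ps <- sample_particles_hardcore(mesh, model, seed = 1)
  expect_identical(nrow(ps), 1415L)
  # brute-force O(n^2) separation check
  P <- cbind(ps$x, ps$y, ps$z)
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  expect_gte(min(D), 13)
  # deterministic for fixed seed
  ps2 <- sample_particles_hardcore(mesh, model, seed = 1)
  expect_identical(ps, ps2)
  expect_false(identical(ps, sample_particles_hardcore(mesh, model, seed = 2)))
})

test_that("density zero gives an empty set; unreachable density errors", {
  mesh <- flat_square_mesh(200, 200, spacing = 10)
  expect_identical(nrow(sample_particles_hardcore(
    mesh, particle_model("PSII", density = 0))), 0L)
  expect_error(sample_particles_hardcore(
    mesh, particle_model("PSII", density = 8000, min_separation = 13)),
    "packing bound")
})

test_that("Poisson-limit nearest neighbors match the 1/(2 sqrt(lambda)) law", {
  # min_separation = 0: ideal Poisson process; NN mean = 1/(2 sqrt(lambda))
  mesh <- flat_square_mesh(1000, 1000, spacing = 20)
  lam <- 1415e-6  # nm^-2
  expect_mean <- 1 / (2 * sqrt(lam))
  means <- sems <- numeric(10)
  for (s in 1:10) {
    ps <- sample_particles_hardcore(mesh,
                                    particle_model("PSII", min_separation = 0),
                                    seed = s)
    nn <- nn_distances(ps, mesh, include_clipped_sources = TRUE)
    means[s] <- nn$summary$mean
    sems[s] <- nn$summary$sem
  }
  pooled_sem <- sqrt(sum(sems^2)) / 10
  expect_lt(abs(mean(means) - expect_mean), 3 * pooled_sem + 0.15)
})

test_that("flat membrane pairs sit at the stated center-to-center distance", {
  fp <- make_flat_membrane_pair(3.2, extent = 150)
  d <- fp$meshes[[2]]$vertices[, 3] - fp$meshes[[1]]$vertices[1, 3]
  expect_equal(unique(round(d, 9)), 3.2 + 5.1)
  fp2 <- make_flat_membrane_pair(10.8, extent = 150)
  expect_equal(diff(fp2$midplanes), 10.8 + 5.1)
  expect_error(make_flat_membrane_pair(0), "gap")
  expect_error(make_flat_membrane_pair(3.2, extent = 0), "extent")
})

test_that("phantom export writes MRC, OBJ, STAR, and a TOML manifest", {
  dir <- withr::local_tempdir()
  p <- geometry_params(granum_radius = 30, lamella_length = 0,
                       volume_shape = c(64, 64, 80), n_thylakoids = 2,
                       mesh_spacing = 5)
  ph <- make_granum_phantom(p)
  ps <- sample_particles_hardcore(ph$truth$meshes[[2]],
                                  particle_model("PSII"), seed = 1)
  write_phantom(ph, dir, particles = ps)
  expect_true(all(file.exists(file.path(
    dir, c("mask.mrc", "density.mrc", "membrane_01.obj",
           "particles.star", "manifest.toml")))))
  man <- readLines(file.path(dir, "manifest.toml"))
  expect_true(any(grepl("membrane_thickness = 5.1", man)))
  back <- read_mrc(file.path(dir, "mask.mrc"))
  expect_identical(back$values, ph$mask$values + 0)
})
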