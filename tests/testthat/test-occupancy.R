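test_that("builtin footprints are valid and ordered by supercomplex size", {
  c2 <- make_footprint("C2")
  c2s2 <- make_footprint("C2S2")
  m2 <- make_footprint("C2S2M2")
  expect_lt(c2$area, c2s2$area)
  expect_lt(c2s2$area, m2$area)
  # two-fold symmetry of the dimer outline
  rot <- rotate_polygon(c2$outline, 180)
  n <- nrow(rot)
  expect_equal(rot[c((n / 2 + 1):n, 1:(n / 2)), ], c2$outline,
               tolerance = 1e-9, ignore_attr = TRUE)
  # area equals its shoelace integral (self-consistency)
  expect_equal(c2$area, polygon_area(c2$outline))
  # full rotation is the identity
  for (v in c("C2S2M2", "S2_trimers_only")) {
    fp <- make_footprint(v)
    expect_equal(rotate_polygon(fp$outline, 360), fp$outline,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("footprints can be derived from an atomic-coordinate file", {
  skip_if_not_installed("bio3d")
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_synthetic_pdb(pdb, a = 8, b = 4, n = 600)
  fp <- make_footprint("C2", structure_file = pdb)
  expect_identical(fp$provenance, "derived-from-structure")
  # half-max outline of a uniform ellipse blurred to 14 A: close to the
  # ellipse itself
  expect_equal(fp$area, pi * 8 * 4, tolerance = 0.25 * pi * 8 * 4)
  expect_true(granametrics:::point_in_polygon_single(c(0, 0), fp$outline))
})

test_that("placed footprints cover their polygon area on the membrane", {
  mesh <- flat_square_mesh(300, 300, spacing = 10)
  c2 <- make_footprint("C2")
  one <- particle_set(data.frame(x = 5, y = -12, z = 0, angle = 33))
  pl <- place_footprints(one, c2, mesh)
  cv <- membrane_coverage(pl, resolution = 0.25)
  expect_equal(cv$union_area, c2$area, tolerance = 0.02 * c2$area)
  # zero particles: empty coverage
  expect_identical(membrane_coverage(
    place_footprints(particle_set(), c2, mesh))$covered_fraction, 0)
  # two far-apart particles: additive
  two <- particle_set(data.frame(x = c(-100, 100), y = 0, z = 0,
                                 angle = c(0, 90)))
  cv2 <- membrane_coverage(place_footprints(two, c2, mesh),
                           resolution = 0.25)
  expect_equal(cv2$union_area, 2 * c2$area, tolerance = 0.02 * c2$area)
})

test_that("in-plane clash matches constructed overlaps and limits", {
  mesh <- flat_square_mesh(300, 300, spacing = 10)
  c2 <- make_footprint("C2")
  # identical pose: intersection = one footprint, total = two
  same <- particle_set(data.frame(x = c(0, 0), y = 0, z = 0, angle = 40))
  expect_equal(in_plane_clash(place_footprints(same, c2, mesh))$clash_fraction,
               0.5, tolerance = 1e-9)
  # beyond both bounding radii: zero
  far <- particle_set(data.frame(x = c(-60, 60), y = 0, z = 0, angle = 0))
  expect_identical(in_plane_clash(place_footprints(far, c2, mesh))$clash_fraction, 0)
  # constructed ~10 percent pairwise overlap, verified against the
  # independent raster oracle
  skip_if_not_installed("mgcv")
  shift <- 17.05
  pair <- particle_set(data.frame(x = c(0, shift), y = 0, z = 0, angle = 0))
  pl <- place_footprints(pair, c2, mesh)
  cl <- in_plane_clash(pl)
  oracle <- oracle_intersection_area(pl$polys[[1]], pl$polys[[2]], px = 0.5)
  expect_equal(cl$pair_area, oracle, tolerance = 0.01 * c2$area)
})

test_that("coverage of a hard-core pattern approximates density times area", {
  mesh <- flat_square_mesh(700, 700, spacing = 10)
  c2 <- make_footprint("C2")
  ps <- sample_particles_hardcore(mesh, particle_model("PSII",
                                                       min_separation = 13),
                                  seed = 2)
  pl <- place_footprints(ps, c2, mesh)
  cv <- membrane_coverage(pl)
  clash <- in_plane_clash(pl)
  naive <- nrow(ps) * c2$area / mesh_area(mesh)
  # union = naive minus the (small) pairwise overlap
  expect_equal(cv$covered_fraction, naive * (1 - clash$clash_fraction),
               tolerance = 0.02 * naive)
})

test_that("raster union agrees with the independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  c2s2 <- make_footprint("C2S2")
  ps <- particle_set(data.frame(x = runif(25, -60, 60),
                                y = runif(25, -60, 60), z = 0,
                                angle = runif(25, 0, 360)))
  mesh <- flat_square_mesh(200, 200, spacing = 10)
  pl <- place_footprints(ps, c2s2, mesh)
  got <- membrane_coverage(pl, resolution = 0.5)$union_area
  oracle <- oracle_union_area(pl$polys, px = 0.5)
  expect_equal(got, oracle, tolerance = 0.01 * oracle)
})

test_that("stack projection translates positions along the stack axis", {
  m1 <- flat_square_mesh(400, 400, spacing = 10)
  m2 <- flat_square_mesh(400, 400, spacing = 10, center = c(0, 0, 8.3))
  ps <- sample_particles_hardcore(m1, particle_model("PSII", density = 600,
                                                     min_separation = 13),
                                  seed = 5)
  up <- ps; up$z <- up$z + 8.3
  pr <- project_stack(list(m1, m2), list(ps, particle_set(up)))
  # identical sets project onto each other exactly
  expect_equal(pr$particles[[2]]$x, pr$particles[[1]]$x, tolerance = 1e-9)
  expect_equal(pr$particles[[2]]$z, pr$particles[[1]]$z, tolerance = 1e-9)
  # a 40 nm lateral shift survives projection
  sh <- ps; sh$z <- sh$z + 8.3; sh$x <- sh$x + 40
  pr2 <- suppressMessages(project_stack(list(m1, m2),
                                        list(ps, particle_set(sh))))
  kept <- pr2$particles[[2]]
  expect_gt(nrow(kept), 0)
  expect_equal(sort(kept$x), sort(ps$x[ps$x + 40 <= 200] + 40),
               tolerance = 1e-9)
})

test_that("inclined stacks are projected obliquely and restricted to shared area", {
  th <- 10 * pi / 180
  m1 <- flat_square_mesh(300, 300, spacing = 10)
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  m2 <- transform_mesh(flat_square_mesh(300, 300, spacing = 10), R,
                       c(0, 0, 10))
  ps2 <- particle_set(data.frame(x = c(0, 50), y = c(0, 20), z = 0,
                                 angle = 0))
  P2 <- cbind(ps2$x, ps2$y, ps2$z) %*% t(R)
  P2[, 3] <- P2[, 3] + 10
  on2 <- particle_set(data.frame(x = P2[, 1], y = P2[, 2], z = P2[, 3]))
  pr <- project_stack(list(m1, m2), list(particle_set(data.frame(
    x = 0, y = 0, z = 0)), on2))
  # analytic oblique projection along the reference normal (z): drop z
  expect_equal(pr$particles[[2]]$x, P2[, 1], tolerance = 1)
  expect_equal(pr$particles[[2]]$y, P2[, 2], tolerance = 1)
  # shared area excludes the non-overlapping margin
  expect_lt(pr$region$area_nm2, 300^2)
})

test_that("cumulative coverage is non-decreasing and matches constructions", {
  m <- list(flat_square_mesh(300, 300, spacing = 10),
            flat_square_mesh(300, 300, spacing = 10, center = c(0, 0, 8.3)))
  c2 <- make_footprint("C2")
  # identical sets on both membranes: constant after the first
  ps <- sample_particles_hardcore(m[[1]], particle_model("PSII",
                                                         min_separation = 13),
                                  seed = 3)
  up <- ps; up$z <- up$z + 8.3
  pr <- project_stack(m, list(ps, particle_set(up)))
  cc <- cumulative_coverage(pr, c2)
  expect_equal(cc[2], cc[1], tolerance = 1e-12)
  # complementary half-plane sets partition the area: 0.5 then 1.0
  g <- expand.grid(x = seq(-140, 140, by = 10), y = seq(-140, 140, by = 10))
  left <- particle_set(data.frame(x = g$x[g$x < 0], y = g$y[g$x < 0], z = 0))
  right <- particle_set(data.frame(x = g$x[g$x >= 0], y = g$y[g$x >= 0],
                                   z = 8.3))
  big <- structure(list(variant = "C2", outline = cbind(
    c(-5, 5, 5, -5), c(-5, -5, 5, 5)), area = 100,
    provenance = "builtin"), class = "footprint")
  pr2 <- project_stack(m, list(left, right))
  cc2 <- cumulative_coverage(pr2, big)
  expect_true(all(diff(cc2) >= -1e-12))
  expect_gt(cc2[2], cc2[1])
})

test_that("independent random layers follow the 1 - (1-f)^n closed form", {
  m <- lapply(0:2, function(k)
    flat_square_mesh(400, 400, spacing = 10, center = c(0, 0, 8.3 * k)))
  c2s2 <- make_footprint("C2S2")
  devs <- numeric(6)
  for (s in 1:6) {
    sets <- lapply(1:3, function(k) {
      ps <- sample_particles_hardcore(m[[k]],
                                      particle_model("PSII",
                                                     min_separation = 13),
                                      seed = 100 * s + k)
      ps$z <- ps$z  # already at membrane height
      ps
    })
    pr <- project_stack(m, sets)
    cc <- cumulative_coverage(pr, c2s2)
    f <- cc[1]
    pred <- 1 - (1 - f)^(1:3)
    devs[s] <- max(abs(cc - pred))
  }
  expect_lt(mean(devs), 0.05)
})

test_that("pair overlap hits the identity, disjoint, and independence limits", {
  m1 <- flat_square_mesh(400, 400, spacing = 10)
  m2 <- flat_square_mesh(400, 400, spacing = 10, center = c(0, 0, 8.3))
  c2s2 <- make_footprint("C2S2")
  ps <- sample_particles_hardcore(m1, particle_model("PSII",
                                                     min_separation = 13),
                                  seed = 8)
  same <- ps; same$z <- same$z + 8.3
  pr <- project_stack(list(m1, m2), list(ps, particle_set(same)))
  plA <- place_footprints(pr$particles[[1]], c2s2, m1, frame = pr$frame)
  plB <- place_footprints(pr$particles[[2]], c2s2, m1, frame = pr$frame)
  expect_equal(pair_overlap(plA, plB, region = pr$region)$overlap_fraction, 1,
               tolerance = 1e-9)
  # disjoint
  off <- ps; off$x <- off$x + 1000
  plC <- place_footprints(particle_set(off), c2s2, m1, frame = pr$frame)
  expect_identical(pair_overlap(plA, plC)$overlap_fraction, 0)
  # independent patterns: overlap of A by B approximates B coverage
  fr <- numeric(5); fb <- numeric(5)
  for (s in 1:5) {
    b <- sample_particles_hardcore(m2, particle_model("PSII",
                                                      min_separation = 13),
                                   seed = 500 + s)
    prs <- project_stack(list(m1, m2), list(ps, b))
    pA <- place_footprints(prs$particles[[1]], c2s2, m1, frame = prs$frame)
    pB <- place_footprints(prs$particles[[2]], c2s2, m1, frame = prs$frame)
    fr[s] <- pair_overlap(pA, pB, region = prs$region)$overlap_fraction
    fb[s] <- membrane_coverage(pB, region = prs$region,
                               analyzed_area = prs$region$area_nm2)$covered_fraction
  }
  expect_lt(abs(mean(fr) - mean(fb)), 0.05)
})

test_that("membranograms sample protrusions at the stated offset", {
  # constant volume -> constant membranogram, nothing above threshold
  vol <- density_volume(array(2, c(40, 40, 40)), 1.5)
  mesh <- flat_square_mesh(30, 30, spacing = 5, center = c(29, 29, 29))
  mg <- render_membranogram(vol, mesh, offset = 2)
  expect_identical(sum(mg$mask), 0L)
  # hemispherical protrusion on one side appears as one connected blob
  fp <- make_flat_membrane_pair(10.8, extent = 80, density = TRUE)
  pm <- particle_model("PSII", protrusion_height = 3, protrusion_radius = 5)
  mesh1 <- flat_square_mesh(60, 60, spacing = 4,
                            center = c(0, 0, fp$midplanes[1]))
  one <- particle_set(data.frame(x = 3, y = -4, z = fp$midplanes[1]))
  vol2 <- add_particle_protrusions(fp$volume, one, mesh1, pm, sign = 1)
  mg2 <- render_membranogram(vol2, mesh1, offset = 2, side = "luminal")
  expect_gt(sum(mg2$mask), 0)
  ctr <- face_centroids(mesh1)[mg2$mask, , drop = FALSE]
  expect_true(all(sqrt((ctr[, 1] - 3)^2 + (ctr[, 2] + 4)^2) < 12))
  # offset far beyond any density: all background
  mg3 <- render_membranogram(vol2, mesh1, offset = 25, side = "luminal")
  expect_identical(sum(mg3$mask), 0L)
  # density-mode pair overlap: identical masks give 1
  ov <- pair_overlap(mg2, mg2, mesh = mesh1, gap_type = "luminal")
  expect_identical(ov$overlap_fraction, 1)
})

test_that("occupancy statistics are invariant under rigid in-plane rotation", {
  mesh <- flat_square_mesh(300, 300, spacing = 10)
  c2s2 <- make_footprint("C2S2")
  ps <- sample_particles_hardcore(mesh, particle_model("PSII", density = 900,
                                                       min_separation = 13),
                                  seed = 13)
  pl <- place_footprints(ps, c2s2, mesh)
  cl0 <- in_plane_clash(pl)$clash_fraction
  cv0 <- membrane_coverage(pl)$covered_fraction
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  meshr <- transform_mesh(mesh, R)
  P <- cbind(ps$x, ps$y, ps$z) %*% t(R)
  psr <- particle_set(data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                                 angle = (ps$angle + 37) %% 360))
  plr <- place_footprints(psr, c2s2, meshr)
  expect_equal(in_plane_clash(plr)$clash_fraction, cl0, tolerance = 1e-6)
  expect_equal(membrane_coverage(plr)$covered_fraction, cv0,
               tolerance = 1e-6)
})
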