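#' Geometry parameters of the granum phantom
#'
#' Defaults reproduce the measured mean geometry of spinach thylakoids:
#' membrane (bilayer) thickness 5.1 nm, stromal gap 3.2 nm, lumen width
#' 10.8 nm, hence a thylakoid thickness of 2 x 5.1 + 10.8 = 21.0 nm
#' (the independently measured value is 21.1 nm), at the bin4 analysis voxel
#' size of 1.408 nm.
#'
#' @param membrane_thickness bilayer thickness (nm).
#' @param stromal_gap surface-to-surface gap between stacked thylakoids (nm).
#' @param lumen_width intra-thylakoid lumen width (nm).
#' @param n_thylakoids number of stacked thylakoid discs.
#' @param granum_radius disc radius (nm).
#' @param lamella_length length of the attached non-appressed lamellar
#'   tongue (nm); 0 disables it. Two mirror-image tongues are attached (top
#'   and bottom outer membranes) so the phantom stays symmetric under
#'   reflection through the stack mid-plane.
#' @param voxel_size rendering voxel size (nm).
#' @param volume_shape length-3 voxel counts (x, y, z).
#' @param noise_sigma additive Gaussian noise, as a fraction of the leaflet
#'   peak intensity (1.0).
#' @param seed RNG seed for the noise field.
#' @param mesh_spacing ground-truth mesh grid spacing (nm).
#' @return an object of class `geometry_params`.
#' @export
geometry_params <- function(membrane_thickness = 5.1, stromal_gap = 3.2,
                            lumen_width = 10.8, n_thylakoids = 3,
                            granum_radius = 60, lamella_length = 60,
                            voxel_size = 1.408,
                            volume_shape = c(144, 112, 112),
                            noise_sigma = 0.1, seed = 1,
                            mesh_spacing = 4) {
  p <- list(membrane_thickness = membrane_thickness,
            stromal_gap = stromal_gap, lumen_width = lumen_width,
            n_thylakoids = as.integer(n_thylakoids),
            granum_radius = granum_radius,
            lamella_length = lamella_length, voxel_size = voxel_size,
            volume_shape = as.integer(rep_len(volume_shape, 3L)),
            noise_sigma = noise_sigma, seed = as.integer(seed),
            mesh_spacing = mesh_spacing)
  for (f in c("membrane_thickness", "stromal_gap", "lumen_width",
              "granum_radius", "voxel_size", "mesh_spacing"))
    if (p[[f]] <= 0) stop(f, " must be > 0")
  if (p$lamella_length < 0) stop("lamella_length must be >= 0")
  if (p$n_thylakoids < 1) stop("n_thylakoids must be >= 1")
  if (p$noise_sigma < 0) stop("noise_sigma must be >= 0")
  p$thylakoid_thickness <- 2 * membrane_thickness + lumen_width
  class(p) <- "geometry_params"
  p
}

#' @export
print.geometry_params <- function(x, ...) {
  cat(sprintf(
    "<geometry_params> membrane %.2f | gap %.2f | lumen %.2f | thylakoid %.2f nm\n",
    x$membrane_thickness, x$stromal_gap, x$lumen_width,
    x$thylakoid_thickness))
  cat(sprintf("  %d thylakoids, radius %.0f nm, lamella %.0f nm, %.3f nm voxels, shape %s\n",
              x$n_thylakoids, x$granum_radius, x$lamella_length,
              x$voxel_size, paste(x$volume_shape, collapse = "x")))
  invisible(x)
}

# membrane midplane z positions and disc center for a parameter set;
# errors name the offending dimension if the geometry does not fit
granum_layout <- function(params) {
  p <- params
  ext <- p$volume_shape * p$voxel_size
  H <- p$n_thylakoids * p$thylakoid_thickness +
    (p$n_thylakoids - 1) * p$stromal_gap
  margin <- 4 * p$voxel_size
  if (2 * p$granum_radius + p$lamella_length + margin > ext[1])
    stop("granum (2*radius + lamella = ",
         2 * p$granum_radius + p$lamella_length,
         " nm) does not fit volume x extent ", ext[1], " nm")
  if (2 * p$granum_radius + margin > ext[2])
    stop("granum diameter ", 2 * p$granum_radius,
         " nm does not fit volume y extent ", ext[2], " nm")
  if (H + margin > ext[3])
    stop("stack height ", H, " nm does not fit volume z extent ",
         ext[3], " nm")
  cx <- (ext[1] - (2 * p$granum_radius + p$lamella_length)) / 2 +
    p$granum_radius - p$voxel_size / 2
  cy <- ext[2] / 2 - p$voxel_size / 2
  z0 <- (ext[3] - H) / 2 - p$voxel_size / 2  # first outer boundary
  mids <- numeric(0); kind <- character(0)
  for (j in seq_len(p$n_thylakoids)) {
    base <- z0 + (j - 1) * (p$thylakoid_thickness + p$stromal_gap)
    mids <- c(mids, base + p$membrane_thickness / 2,
              base + p$membrane_thickness * 1.5 + p$lumen_width)
    kind <- c(kind, "lower", "upper")
  }
  list(center = c(cx, cy), midplanes = mids, kind = kind,
       stack_height = H, z0 = z0)
}

# asymmetric leaflet pair: outer flank half-width t/4 (half-maximum exactly
# at +/- t/2, the nominal membrane boundary), inner flank half-width t/8
# (resolves the two leaflets with a central dip)
bilayer_profile <- function(dz, t) {
  wo <- t / 4; wi <- t / 8; cc <- t / 4
  leaflet <- function(u) {  # u: signed offset from leaflet center, + = outward
    val <- numeric(length(u))
    o <- u >= 0 & u <= 2 * wo
    val[o] <- cos(pi * u[o] / (4 * wo))^2
    i <- u < 0 & u >= -2 * wi
    val[i] <- cos(pi * u[i] / (4 * wi))^2
    val
  }
  leaflet(dz - cc) + leaflet(-(dz + cc))
}

#' Generate a multilamellar granum phantom
#'
#' Builds a stack of `n_thylakoids` thylakoid discs along z: each disc is a
#' pair of bilayer membranes enclosing the lumen, adjacent discs are
#' separated by the stromal gap, and (optionally) mirror-image non-appressed
#' lamellar tongues extend from the outer membranes. Returns the binary
#' membrane voxel mask, a density map in which each bilayer is rendered as
#' two leaflet peaks whose outer half-maximum crossings are separated by
#' exactly `membrane_thickness` (so the morphometry edge correction is
#' exactly recoverable), and the ground truth: one midplane mesh per
#' membrane with per-face appressed/non-appressed labels.
#'
#' Membranes are rendered bright (high intensity); use `invert_contrast` in
#' analysis functions for conventional dark-on-light cryo-ET contrast.
#'
#' @param params a [geometry_params].
#' @param density logical; render the density map (skip for mesh-only use).
#' @return list with elements `mask` ([density_volume], 0/1), `density`
#'   ([density_volume] or NULL), and `truth` (list: `meshes`, per-face
#'   `labels` inside each mesh, `midplanes`, `params`).
#' @export
make_granum_phantom <- function(params = geometry_params(), density = TRUE) {
  p <- params
  lay <- granum_layout(p)
  n_m <- length(lay$midplanes)
  ext <- p$volume_shape * p$voxel_size
  # ground-truth meshes: outermost membranes (first lower, last upper) carry
  # the lamellar tongue and are non-appressed; interior membranes appressed
  meshes <- vector("list", n_m)
  for (i in seq_len(n_m)) {
    outer_m <- i == 1L || i == n_m
    tongue <- if (outer_m && p$lamella_length > 0) p$lamella_length else 0
    m <- disc_mesh(p$granum_radius, spacing = p$mesh_spacing,
                   center = c(lay$center, lay$midplanes[i]),
                   tongue_length = tongue,
                   tongue_width = p$granum_radius)
    lab <- rep(if (outer_m || p$n_thylakoids == 1L) "non_appressed"
               else "appressed", nrow(m$faces))
    m$labels <- lab
    meshes[[i]] <- m
  }
  # voxel world z coordinates (origin at 0)
  zs <- (seq_len(p$volume_shape[3]) - 1) * p$voxel_size
  xs <- (seq_len(p$volume_shape[1]) - 1) * p$voxel_size
  ys <- (seq_len(p$volume_shape[2]) - 1) * p$voxel_size
  r2 <- outer((xs - lay$center[1])^2, (ys - lay$center[2])^2, "+")
  disc2d <- r2 <= p$granum_radius^2
  tongue2d <- if (p$lamella_length > 0) {
    outer(xs >= lay$center[1] &
            xs <= lay$center[1] + p$granum_radius + p$lamella_length,
          abs(ys - lay$center[2]) <= p$granum_radius / 2, "&")
  } else NULL
  mask <- array(0L, p$volume_shape)
  dens <- if (density) array(0, p$volume_shape) else NULL
  for (i in seq_len(n_m)) {
    outer_m <- i == 1L || i == n_m
    region <- if (outer_m && !is.null(tongue2d)) disc2d | tongue2d else disc2d
    dz <- zs - lay$midplanes[i]
    in_mask <- which(abs(dz) <= p$membrane_thickness / 2)
    for (k in in_mask) mask[, , k] <- mask[, , k] | region
    if (density) {
      prof <- bilayer_profile(dz, p$membrane_thickness)
      in_prof <- which(prof > 0)
      for (k in in_prof) dens[, , k] <- dens[, , k] + region * prof[k]
    }
  }
  storage.mode(mask) <- "integer"
  if (density && p$noise_sigma > 0) {
    set.seed(p$seed)
    dens <- dens + array(rnorm(length(dens), 0, p$noise_sigma), dim(dens))
  }
  list(
    mask = density_volume(mask, p$voxel_size),
    density = if (density) density_volume(dens, p$voxel_size) else NULL,
    truth = list(meshes = meshes, midplanes = lay$midplanes,
                 center = lay$center, params = p)
  )
}

#' Ground-truth appressed / non-appressed areas of a phantom
#'
#' @param truth the `truth` element of [make_granum_phantom()].
#' @return named vector (nm^2): `appressed`, `non_appressed`, `ratio`.
#' @export
phantom_truth_areas <- function(truth) {
  app <- 0; non <- 0
  for (m in truth$meshes) {
    app <- app + sum(m$areas[m$labels == "appressed"])
    non <- non + sum(m$areas[m$labels == "non_appressed"])
  }
  c(appressed = app, non_appressed = non,
    ratio = if (non > 0) app / non else Inf)
}

#' Particle model for surface point processes
#'
#' Default densities are the measured appressed-membrane concentrations in
#' spinach grana: all particles 2160, PSII 1415, cytochrome b6f 446 per
#' square micron. The default hard-core separation of 13 nm is the scale of
#' the PSII core dimer footprint.
#'
#' @param class_label particle class (`PSII`, `cytb6f`, `unknown`).
#' @param density target count per square micron; `NULL` looks up the
#'   reference density for `class_label`.
#' @param min_separation hard-core center-to-center distance (nm).
#' @param protrusion_height,protrusion_radius size of the protruding density
#'   rendered for membranogram tests (nm).
#' @param side which membrane face the density protrudes from.
#' @return an object of class `particle_model`.
#' @export
particle_model <- function(class_label = "PSII", density = NULL,
                           min_separation = 13, protrusion_height = 3,
                           protrusion_radius = 5,
                           side = c("luminal", "stromal")) {
  side <- match.arg(side)
  if (is.null(density)) {
    ref <- reference_densities()
    density <- if (class_label %in% names(ref)) ref[[class_label]] else ref[["all"]]
  }
  if (density < 0) stop("density must be >= 0")
  if (min_separation < 0) stop("min_separation must be >= 0")
  structure(list(class_label = class_label, density = density,
                 min_separation = min_separation,
                 protrusion_height = protrusion_height,
                 protrusion_radius = protrusion_radius, side = side),
            class = "particle_model")
}

#' @rdname particle_model
#' @export
reference_densities <- function() {
  c(all = 2160, PSII = 1415, cytb6f = 446)
}

#' Hard-core dart-throwing sampler on a mesh
#'
#' Draws `round(density x mesh area)` particle positions uniformly by area
#' with rejection of any dart closer than `min_separation` (3D chord
#' distance; on the near-planar phantom membranes the chord and geodesic
#' separations coincide, and chord >= min implies geodesic >= min).
#' Orientations are uniform in \[0, 360). Particles within
#' `protrusion_radius` of an open mesh boundary are flagged `clipped`.
#'
#' @param mesh a [tri_mesh].
#' @param model a [particle_model].
#' @param seed RNG seed; fixed seed gives identical output.
#' @param membrane_id membrane id stored with the particles.
#' @param max_attempts_per_particle rejection budget.
#' @return a [particle_set()].
#' @export
sample_particles_hardcore <- function(mesh, model, seed = 1,
                                      membrane_id = "m1",
                                      max_attempts_per_particle = 400) {
  area <- mesh_area(mesh)
  target <- round(model$density * 1e-6 * area)
  if (target == 0) return(particle_set())
  d <- model$min_separation
  if (d > 0) {
    lambda_max <- 2 / (sqrt(3) * d^2)  # hexagonal hard-disc packing bound
    if (model$density * 1e-6 > lambda_max)
      stop(sprintf(
        "density %.0f/um^2 exceeds the hard-disc packing bound %.0f/um^2 at min_separation %.1f nm",
        model$density, lambda_max * 1e6, d))
  }
  set.seed(seed)
  cum <- cumsum(mesh$areas) / area
  pos <- matrix(NA_real_, target, 3)
  n_acc <- 0L
  attempts <- 0L
  max_att <- max_attempts_per_particle * target
  while (n_acc < target && attempts < max_att) {
    attempts <- attempts + 1L
    f <- findInterval(runif(1), cum) + 1L
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    r1 <- sqrt(runif(1)); r2 <- runif(1)
    pt <- (1 - r1) * tri[1, ] + r1 * (1 - r2) * tri[2, ] + r1 * r2 * tri[3, ]
    if (d > 0 && n_acc > 0L) {
      dx <- pos[seq_len(n_acc), 1] - pt[1]
      dy <- pos[seq_len(n_acc), 2] - pt[2]
      dzz <- pos[seq_len(n_acc), 3] - pt[3]
      if (min(dx * dx + dy * dy + dzz * dzz) < d * d) next
    }
    n_acc <- n_acc + 1L
    pos[n_acc, ] <- pt
  }
  if (n_acc < target)
    stop(sprintf(
      "hard-core sampling reached only %d of %d particles (achieved density %.0f/um^2)",
      n_acc, target, n_acc / (area * 1e-6)))
  clip <- rep(FALSE, target)
  be <- boundary_edges(mesh)
  if (nrow(be) > 0 && model$protrusion_radius > 0) {
    dmin <- point_segments_distance(pos, mesh$vertices[be[, 1], , drop = FALSE],
                                    mesh$vertices[be[, 2], , drop = FALSE])
    clip <- dmin < model$protrusion_radius
  }
  particle_set(data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    angle = runif(target) * 360,
    class = model$class_label, membrane = membrane_id, clipped = clip,
    stringsAsFactors = FALSE))
}

# minimum distance from each point to a set of segments (A[i,]-B[i,])
point_segments_distance <- function(pts, A, B) {
  n <- nrow(pts)
  out <- rep(Inf, n)
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1e-300
  for (i in seq_len(n)) {
    AP <- sweep(-A, 2, pts[i, ], "+")   # pts[i] - A
    t <- pmin(pmax(rowSums(AP * AB) / len2, 0), 1)
    Q <- A + AB * t
    out[i] <- sqrt(min(rowSums(sweep(Q, 2, pts[i, ], "-")^2)))
  }
  out
}

#' Minimal two-membrane fixture
#'
#' Two parallel planar membrane meshes at a surface-to-surface gap of `gap`
#' (center-to-center distance `gap + membrane_thickness`), plus an optional
#' rendered density volume. The standard fixture for domain classification
#' and overlap tests.
#'
#' @param gap surface-to-surface gap (nm); the stromal gap is 3.2, the
#'   lumen 10.8.
#' @param extent lateral side length (nm).
#' @param voxel_size voxel size for the rendered volume (nm).
#' @param membrane_thickness bilayer thickness (nm).
#' @param spacing mesh grid spacing (nm).
#' @param density logical; render the two bilayers into a volume.
#' @return list with `meshes` (two [tri_mesh]), `volume` (or NULL), and
#'   `midplanes` (the two z positions, nm).
#' @export
make_flat_membrane_pair <- function(gap, extent = 200, voxel_size = 1.408,
                                    membrane_thickness = 5.1, spacing = 4,
                                    density = FALSE, noise_sigma = 0,
                                    seed = 1) {
  if (gap <= 0) stop("gap must be > 0")
  if (extent <= 0) stop("extent must be > 0")
  c2c <- gap + membrane_thickness
  zmid <- c(-c2c / 2, c2c / 2)
  meshes <- lapply(zmid, function(z)
    flat_square_mesh(extent, extent, spacing = spacing, center = c(0, 0, z)))
  vol <- NULL
  if (density) {
    margin <- 8 * voxel_size
    nxy <- ceiling((extent + 2 * margin) / voxel_size)
    nz <- ceiling((c2c + 2 * membrane_thickness + 2 * margin) / voxel_size)
    org <- c(-(nxy - 1) / 2 * voxel_size, -(nxy - 1) / 2 * voxel_size,
             -(nz - 1) / 2 * voxel_size)
    zs <- org[3] + (seq_len(nz) - 1) * voxel_size
    arr <- array(0, c(nxy, nxy, nz))
    for (z0 in zmid) {
      prof <- bilayer_profile(zs - z0, membrane_thickness)
      for (k in which(prof > 0)) arr[, , k] <- arr[, , k] + prof[k]
    }
    if (noise_sigma > 0) {
      set.seed(seed)
      arr <- arr + array(rnorm(length(arr), 0, noise_sigma), dim(arr))
    }
    vol <- density_volume(arr, voxel_size, origin = org)
  }
  list(meshes = meshes, volume = vol, midplanes = zmid)
}

#' Render particle protrusions into a phantom volume
#'
#' Adds a smooth blob (Gaussian, sigma = `protrusion_radius / 2`) for every
#' particle, centered `membrane_thickness / 2 + protrusion_height / 2` away
#' from the particle position along `sign` times the local face normal.
#' Used to emulate lumen-protruding oxygen-evolving complexes for
#' membranogram tests.
#'
#' @param vol a [density_volume].
#' @param particles a [particle_set()].
#' @param mesh the membrane [tri_mesh].
#' @param model a [particle_model].
#' @param sign +1 to protrude along the face normal, -1 against it.
#' @param membrane_thickness bilayer thickness (nm).
#' @param amplitude peak added intensity.
#' @return the modified [density_volume].
#' @export
add_particle_protrusions <- function(vol, particles, mesh, model, sign = 1,
                                     membrane_thickness = 5.1,
                                     amplitude = 1) {
  if (nrow(particles) == 0) return(vol)
  snap <- snap_to_mesh(mesh, particle_positions(particles))
  sg <- model$protrusion_radius / 2
  off <- membrane_thickness / 2 + model$protrusion_height / 2
  d <- dim(vol$values)
  ax <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$voxel_size[1]
  ay <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$voxel_size[2]
  az <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$voxel_size[3]
  for (i in seq_len(nrow(particles))) {
    nrm <- mesh$normals[snap$face[i], ]
    ctr <- c(particles$x[i], particles$y[i], particles$z[i]) + sign * off * nrm
    ix <- which(abs(ax - ctr[1]) < 3 * sg)
    iy <- which(abs(ay - ctr[2]) < 3 * sg)
    iz <- which(abs(az - ctr[3]) < 3 * sg)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(ax[ix] - ctr[1])^2 / (2 * sg^2))
    gy <- exp(-(ay[iy] - ctr[2])^2 / (2 * sg^2))
    gz <- exp(-(az[iz] - ctr[3])^2 / (2 * sg^2))
    blob <- amplitude * outer(outer(gx, gy), gz)
    vol$values[ix, iy, iz] <- vol$values[ix, iy, iz] + blob
  }
  vol
}
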