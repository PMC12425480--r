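#' Configuration for membrane flattening and profile extraction
#'
#' @param patch_size lateral patch size for profile averaging (nm).
#' @param sample_spacing grid spacing of sample points on the membrane (nm).
#' @param z_range profiles span \[-z_range, +z_range\] along the normal (nm).
#' @param z_step profile step (nm); `NULL` uses a quarter of the volume
#'   voxel size (trilinear interpolation resolves below the voxel scale).
#' @param prominence peak prominence floor as a fraction of the profile
#'   dynamic range.
#' @param merge_within peaks closer than this are grouped into one bilayer
#'   (nm); slightly above the leaflet peak-to-peak spacing.
#' @param gap_split boundary-to-boundary gaps below this value are
#'   classified stromal, above it luminal (nm); midway between the
#'   3.2 nm stromal gap and the 10.8 nm lumen.
#' @param invert_contrast set TRUE when membranes are dark (conventional
#'   cryo-ET contrast); profiles are sign-flipped before analysis.
#' @return an object of class `flattening_config`.
#' @export
flattening_config <- function(patch_size = 50, sample_spacing = 2,
                              z_range = 40, z_step = NULL,
                              prominence = 0.1, merge_within = 4,
                              gap_split = 7, invert_contrast = FALSE) {
  if (patch_size <= 0) stop("patch_size must be > 0")
  structure(list(patch_size = patch_size, sample_spacing = sample_spacing,
                 z_range = z_range, z_step = z_step,
                 prominence = prominence, merge_within = merge_within,
                 gap_split = gap_split, invert_contrast = invert_contrast),
            class = "flattening_config")
}

#' Sample normal-direction image stacks over a membrane
#'
#' Lays a regular grid (spacing `sample_spacing`) over the membrane in its
#' best-fit plane, snaps each grid point to the mesh, and samples the volume
#' by trilinear interpolation at offsets z in \[-z_range, z_range\] along the
#' local face normal. Grid points are grouped into `patch_size` square
#' patches; samples outside the volume are `NA` (masked). Patches whose
#' samples are entirely outside the volume are dropped with a message.
#'
#' @param volume a [density_volume].
#' @param mesh the membrane [tri_mesh].
#' @param cfg a [flattening_config].
#' @return list of patch stacks: each has `patch_id`, `points` (on-mesh
#'   sample positions), `z` (offsets, nm), `samples` (points x z matrix).
#' @export
sample_normal_stack <- function(volume, mesh, cfg = flattening_config()) {
  zstep <- if (is.null(cfg$z_step)) min(volume$voxel_size) / 4 else cfg$z_step
  zoff <- seq(-cfg$z_range, cfg$z_range, by = zstep)
  # membrane-plane frame by PCA of the vertices
  ctr <- colMeans(mesh$vertices)
  sv <- svd(sweep(mesh$vertices, 2, ctr, "-"), nu = 0, nv = 3)
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm0 <- sv$v[, 3]
  uv <- sweep(mesh$vertices, 2, ctr, "-") %*% cbind(e1, e2)
  us <- seq(min(uv[, 1]), max(uv[, 1]), by = cfg$sample_spacing)
  vs <- seq(min(uv[, 2]), max(uv[, 2]), by = cfg$sample_spacing)
  grid <- cbind(rep(us, times = length(vs)), rep(vs, each = length(us)))
  # project grid points onto the mesh along the plane normal
  orig <- sweep(grid %*% t(cbind(e1, e2)), 2, ctr, "+")
  hits <- .trace_rays(orig, matrix(nrm0, nrow(orig), 3, byrow = TRUE),
                      mesh$vertices, mesh$faces,
                      rep(list(integer(0)), nrow(orig)), eps = -1)
  on_mesh <- is.finite(hits$distance)
  if (!any(on_mesh)) stop("no grid point projects onto the mesh")
  fidx <- hits$face[on_mesh]
  # signed offset along the ray to the hit point
  tt <- hits$distance[on_mesh]
  # distance is |t|; recover sign by testing both
  base <- orig[on_mesh, , drop = FALSE]
  ctrs <- face_centroids(mesh)
  dplus <- rowSums((base + tt * matrix(nrm0, length(tt), 3, byrow = TRUE) -
                      ctrs[fidx, , drop = FALSE])^2)
  dminus <- rowSums((base - tt * matrix(nrm0, length(tt), 3, byrow = TRUE) -
                       ctrs[fidx, , drop = FALSE])^2)
  sgn <- ifelse(dplus <= dminus, 1, -1)
  pts <- base + (sgn * tt) * matrix(nrm0, length(tt), 3, byrow = TRUE)
  nrms <- mesh$normals[fidx, , drop = FALSE]
  # patch ids from plane coordinates
  guv <- grid[on_mesh, , drop = FALSE]
  pid <- paste(floor((guv[, 1] - min(us)) / cfg$patch_size),
               floor((guv[, 2] - min(vs)) / cfg$patch_size), sep = "_")
  out <- list()
  for (id in unique(pid)) {
    sel <- pid == id
    P <- pts[sel, , drop = FALSE]
    Nn <- nrms[sel, , drop = FALSE]
    qry <- P[rep(seq_len(nrow(P)), times = length(zoff)), , drop = FALSE] +
      Nn[rep(seq_len(nrow(P)), times = length(zoff)), , drop = FALSE] *
      rep(zoff, each = nrow(P))
    smp <- matrix(sample_volume(volume, qry), nrow(P), length(zoff))
    if (all(is.na(smp))) {
      message("sample_normal_stack: patch ", id,
              " entirely outside the volume; dropped")
      next
    }
    if (cfg$invert_contrast) smp <- -smp
    out[[length(out) + 1L]] <- list(patch_id = id, points = P, z = zoff,
                                    samples = smp,
                                    voxel_nm = min(volume$voxel_size))
  }
  out
}

#' Average a patch stack into a 1D intensity profile
#'
#' Masked mean over the patch at each normal offset, then a 3-sample box
#' smoothing before keypoint search.
#'
#' @param stack one element of [sample_normal_stack()].
#' @return an `intensity_profile`: `z`, `intensity` (smoothed), `raw`,
#'   `patch_id`, `n_samples` per offset.
#' @export
profile_from_stack <- function(stack) {
  if (is.null(stack$samples) || nrow(stack$samples) == 0)
    stop("empty stack")
  mu <- colMeans(stack$samples, na.rm = TRUE)
  n <- colSums(!is.na(stack$samples))
  mu[n == 0] <- NA
  sm <- mu
  ok <- which(!is.na(mu))
  if (length(ok) >= 3) {
    v <- mu[ok]
    sm[ok] <- c(v[1], (v[-c(1, length(v))] * 1 +
                         v[-c(length(v) - 1, length(v))] +
                         v[-c(1, 2)]) / 3, v[length(v)])
  }
  structure(list(z = stack$z, intensity = sm, raw = mu,
                 patch_id = stack$patch_id, n_samples = n,
                 voxel_nm = stack$voxel_nm),
            class = "intensity_profile")
}

#' Detect bilayer keypoints in an intensity profile
#'
#' Local maxima with prominence above `prominence` times the profile
#' dynamic range are leaflet peaks; peaks closer than `merge_within` are
#' grouped into one bilayer. Troughs between consecutive bilayers are
#' reported as gap keypoints. Profiles without any acceptable peak are
#' flagged for exclusion.
#'
#' @param profile an `intensity_profile`.
#' @param cfg a [flattening_config].
#' @return list: `peaks` (data.frame z, intensity, bilayer), `bilayers`
#'   (data.frame center, from, to), `troughs` (z, intensity), `flagged`.
#' @export
detect_keypoints <- function(profile, cfg = flattening_config()) {
  z <- profile$z; y <- profile$intensity
  ok <- !is.na(y)
  if (sum(ok) < 5)
    return(list(peaks = NULL, bilayers = NULL, troughs = NULL,
                flagged = TRUE))
  zz <- z[ok]; yy <- y[ok]
  rng <- max(yy) - min(yy)
  if (rng <= 0)
    return(list(peaks = NULL, bilayers = NULL, troughs = NULL,
                flagged = TRUE))
  n <- length(yy)
  is_max <- c(FALSE, yy[2:(n - 1)] >= yy[1:(n - 2)] &
                yy[2:(n - 1)] >= yy[3:n], FALSE)
  cand <- which(is_max)
  # prominence: drop to the higher of the two bounding minima
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    lmin <- min(yy[1:p]); rmin <- min(yy[p:n])
    keep[i] <- (yy[p] - max(lmin, rmin)) >= cfg$prominence * rng
  }
  cand <- cand[keep]
  if (length(cand) == 0)
    return(list(peaks = NULL, bilayers = NULL, troughs = NULL,
                flagged = TRUE))
  # merge plateau/duplicate peaks closer than one step
  pk <- data.frame(z = zz[cand], intensity = yy[cand])
  pk <- pk[order(pk$z), , drop = FALSE]
  # drop peaks whose flank is truncated by the profile window: a bilayer cut
  # by the z range would otherwise fake a spuriously thin membrane
  full <- pk$z - min(zz) > cfg$merge_within & max(zz) - pk$z > cfg$merge_within
  pk <- pk[full, , drop = FALSE]
  if (nrow(pk) == 0)
    return(list(peaks = NULL, bilayers = NULL, troughs = NULL,
                flagged = TRUE))
  grp <- cumsum(c(1, diff(pk$z) > cfg$merge_within))
  pk$bilayer <- grp
  bil <- do.call(rbind, lapply(split(pk, grp), function(d) {
    data.frame(center = mean(range(d$z)), from = min(d$z), to = max(d$z),
               peak_intensity = max(d$intensity))
  }))
  troughs <- NULL
  if (nrow(bil) >= 2) {
    tr <- vapply(seq_len(nrow(bil) - 1L), function(i) {
      sel <- zz > bil$to[i] & zz < bil$from[i + 1L]
      if (!any(sel)) return(NA_real_)
      zz[sel][which.min(yy[sel])]
    }, 0)
    ti <- vapply(seq_len(nrow(bil) - 1L), function(i) {
      sel <- zz > bil$to[i] & zz < bil$from[i + 1L]
      if (!any(sel)) return(NA_real_)
      min(yy[sel])
    }, 0)
    troughs <- data.frame(z = tr, intensity = ti)
  }
  list(peaks = pk, bilayers = bil, troughs = troughs, flagged = FALSE)
}

#' Half-maximum edge correction of bilayer boundaries
#'
#' For each detected bilayer, the membrane boundary on each side is placed
#' at the half-amplitude crossing of the outer leaflet flank: the amplitude
#' is measured from the outer leaflet peak down to the local baseline on
#' that side (the minimum between this bilayer and its neighbor, or the
#' profile end), and the crossing is located by linear interpolation. The
#' correction is applied symmetrically on both sides; membrane thickness is
#' the distance between the two outer boundaries.
#'
#' @param profile an `intensity_profile`.
#' @param keypoints result of [detect_keypoints()].
#' @return data.frame per bilayer: `center`, `left_edge`, `right_edge`,
#'   `thickness`, `flagged` (flank never crossed half amplitude).
#' @export
half_max_edge_correct <- function(profile, keypoints) {
  if (is.null(keypoints$bilayers)) return(NULL)
  # crossings are located on the raw masked-mean profile: the 3-sample box
  # smoothing used for keypoint search biases half-max crossings inward on
  # concave flanks
  z <- profile$z
  y <- if (!is.null(profile$raw)) profile$raw else profile$intensity
  ok <- !is.na(y); zz <- z[ok]; yy <- y[ok]
  bil <- keypoints$bilayers
  pk <- keypoints$peaks
  out <- bil
  out$left_edge <- NA_real_; out$right_edge <- NA_real_
  out$flagged <- FALSE
  for (i in seq_len(nrow(bil))) {
    mypk <- pk[pk$bilayer == i, , drop = FALSE]
    # outer leaflet peak on each side; amplitude re-read from the raw
    # profile with parabolic sub-sample refinement (sampling lowers the
    # apparent peak, which would push the half-max crossing outward)
    lz <- min(mypk$z); rz <- max(mypk$z)
    vox <- if (!is.null(profile$voxel_nm)) profile$voxel_nm else
      4 * stats::median(diff(zz))
    lpkv <- peak_amplitude(zz, yy, lz, spacing = vox)
    rpkv <- peak_amplitude(zz, yy, rz, spacing = vox)
    # local baselines
    lbound <- if (i > 1) bil$to[i - 1] else min(zz)
    rbound <- if (i < nrow(bil)) bil$from[i + 1] else max(zz)
    lsel <- zz >= lbound & zz < lz
    rsel <- zz > rz & zz <= rbound
    lbase <- if (any(lsel)) min(yy[lsel]) else NA
    rbase <- if (any(rsel)) min(yy[rsel]) else NA
    lhalf <- lbase + (lpkv - lbase) / 2
    rhalf <- rbase + (rpkv - rbase) / 2
    out$left_edge[i] <- flank_crossing(zz, yy, from = lz, level = lhalf,
                                       dir = -1L)
    out$right_edge[i] <- flank_crossing(zz, yy, from = rz, level = rhalf,
                                        dir = +1L)
    out$flagged[i] <- is.na(out$left_edge[i]) || is.na(out$right_edge[i])
  }
  out$thickness <- out$right_edge - out$left_edge
  out
}

# peak amplitude near z = at: local max of the raw samples refined by a
# parabola through three points one voxel apart (the profile is
# piecewise-linear between voxel-scale knots, so closer points are
# collinear and carry no curvature information)
peak_amplitude <- function(zz, yy, at, spacing) {
  sel <- which(abs(zz - at) <= spacing / 2)
  if (length(sel) < 1) return(yy[which.min(abs(zz - at))])
  i <- sel[which.max(yy[sel])]
  i1 <- which.min(abs(zz - (zz[i] - spacing)))
  i3 <- which.min(abs(zz - (zz[i] + spacing)))
  y1 <- yy[i1]; y2 <- yy[i]; y3 <- yy[i3]
  if (i1 == i || i3 == i) return(y2)
  den <- y1 - 2 * y2 + y3
  if (den >= 0) return(y2)  # not concave: keep the sample value
  y2 - (y1 - y3)^2 / (8 * den)
}

# first crossing of `level` walking from z = from in direction dir
flank_crossing <- function(zz, yy, from, level, dir) {
  if (is.na(level)) return(NA_real_)
  i0 <- which.min(abs(zz - from))
  idx <- if (dir > 0) seq(i0, length(zz)) else seq(i0, 1)
  yv <- yy[idx]; zv <- zz[idx]
  below <- which(yv <= level)
  if (length(below) == 0 || below[1] == 1) return(NA_real_)
  b <- below[1]
  z1 <- zv[b - 1]; z2 <- zv[b]; y1 <- yv[b - 1]; y2 <- yv[b]
  if (y2 == y1) return(z2)
  z1 + (level - y1) / (y2 - y1) * (z2 - z1)
}

#' Measure membrane, gap, lumen, and thylakoid spacings
#'
#' Per surviving patch profile: membrane thickness = corrected bilayer
#' width; boundary-to-boundary gaps between consecutive bilayers are
#' classified stromal (< `gap_split`) or luminal; thylakoid thickness spans
#' outer boundary to outer boundary across each luminal gap (measured
#' independently of the membrane and lumen values). Aggregates are mean and
#' SEM over patches; quantities whose keypoint pattern is absent are
#' reported `NA`, never zero.
#'
#' @param profiles list of `intensity_profile`.
#' @param cfg a [flattening_config].
#' @return object of class `spacing_measurement`: `per_patch` data frame
#'   and `summary` (mean, sem, n per quantity).
#' @export
measure_spacings <- function(profiles, cfg = flattening_config()) {
  rows <- list()
  for (pr in profiles) {
    kp <- detect_keypoints(pr, cfg)
    if (kp$flagged) next
    hm <- half_max_edge_correct(pr, kp)
    if (is.null(hm) || all(hm$flagged)) next
    hm <- hm[!hm$flagged, , drop = FALSE]
    membrane <- mean(hm$thickness)
    stromal <- luminal <- thylakoid <- NA_real_
    if (nrow(hm) >= 2) {
      gaps <- hm$left_edge[-1] - hm$right_edge[-nrow(hm)]
      kind <- ifelse(gaps < cfg$gap_split, "stromal", "luminal")
      if (any(kind == "stromal")) stromal <- mean(gaps[kind == "stromal"])
      if (any(kind == "luminal")) {
        luminal <- mean(gaps[kind == "luminal"])
        idx <- which(kind == "luminal")
        thylakoid <- mean(hm$right_edge[idx + 1L] - hm$left_edge[idx])
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patch_id = pr$patch_id, n_bilayers = nrow(hm),
      membrane_thickness = membrane, stromal_gap = stromal,
      lumen_width = luminal, thylakoid_thickness = thylakoid,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("no patch profile survived keypoint validation")
  per_patch <- do.call(rbind, rows)
  qty <- c("membrane_thickness", "stromal_gap", "lumen_width",
           "thylakoid_thickness")
  summ <- do.call(rbind, lapply(qty, function(q) {
    v <- per_patch[[q]]
    v <- v[!is.na(v)]
    data.frame(quantity = q,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  structure(list(per_patch = per_patch, summary = summ),
            class = "spacing_measurement")
}

#' @export
print.spacing_measurement <- function(x, ...) {
  cat("<spacing_measurement> (nm)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %6.2f +/- %.3f  (n=%d)\n", s$quantity[i],
                s$mean[i], s$sem[i], s$n[i]))
  invisible(x)
}

#' One-call morphometry over a membrane
#'
#' [sample_normal_stack()] + [profile_from_stack()] + [measure_spacings()].
#'
#' @param volume a [density_volume].
#' @param mesh membrane [tri_mesh] (profiles are taken along its normals).
#' @param cfg a [flattening_config].
#' @return a `spacing_measurement`.
#' @export
measure_membrane_morphometry <- function(volume, mesh,
                                         cfg = flattening_config()) {
  stacks <- sample_normal_stack(volume, mesh, cfg)
  profiles <- lapply(stacks, profile_from_stack)
  measure_spacings(profiles, cfg)
}
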