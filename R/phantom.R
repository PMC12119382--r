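# Synthetic frame-CT phantoms: an air background, an ellipsoidal head with
# optional skull shell, and the two N-shaped localizer plates rasterized as
# cylinders at a known rigid pose. Ground truth (posed vertices, pose,
# optional marker centre) is returned alongside, so detection, registration
# and planning can be validated end to end without clinical data.

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

#' Phantom configuration
#'
#' Defaults emulate a desk-scale 1 mm acquisition: a 256 x 256 x 200 grid
#' (large enough to hold the default 190 x 120 mm frame with poses up to
#' about 15 degrees / 20 mm), 1.5 mm-radius localizer rods at 2500 HU (well
#' above the 500 HU tracking threshold), a soft-tissue head ellipsoid and an
#' optional 5 mm skull shell at 1000 HU.
#'
#' @param dims Voxel counts per axis.
#' @param spacing mm per axis (scalar or length 3).
#' @param frame A [frame_spec()].
#' @param pose A [rigid_transform()] placing the frame in the scanner.
#' @param rod_radius Localizer rod radius, mm.
#' @param rod_hu Rod intensity, HU (must exceed the tracking threshold).
#' @param head_semiaxes Head ellipsoid semi-axes (R, A, S), mm.
#' @param tissue_hu Head tissue intensity, HU.
#' @param skull Whether to add a skull shell.
#' @param skull_hu,skull_thickness Shell intensity (HU) and thickness (mm).
#' @param noise_sigma Additive Gaussian noise SD, HU (0 = noiseless).
#' @param smooth_fwhm_mm Optional isotropic Gaussian smoothing FWHM, mm
#'   (0 = sharp voxel-centre rasterization, exactly reproducible).
#' @param rng_seed Seed for the noise generator.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(256, 256, 200), spacing = 1,
                           frame = frame_spec(),
                           pose = rigid_transform(),
                           rod_radius = 1.5, rod_hu = 2500,
                           head_semiaxes = c(70, 85, 75), tissue_hu = 40,
                           skull = TRUE, skull_hu = 1000,
                           skull_thickness = 5,
                           noise_sigma = 0, smooth_fwhm_mm = 0,
                           rng_seed = 1L) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(dims) == 3, all(dims >= 2), all(spacing > 0),
            inherits(frame, "frame_spec"), inherits(pose, "rigid_transform"),
            rod_radius > 0, length(head_semiaxes) == 3,
            noise_sigma >= 0, smooth_fwhm_mm >= 0)
  if (rod_hu <= 500)
    stop("phantom_config: rod_hu must exceed the 500 HU tracking threshold",
         call. = FALSE)
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 frame = frame, pose = pose,
                 rod_radius = rod_radius, rod_hu = rod_hu,
                 head_semiaxes = as.numeric(head_semiaxes),
                 tissue_hu = tissue_hu, skull = isTRUE(skull),
                 skull_hu = skull_hu, skull_thickness = skull_thickness,
                 noise_sigma = noise_sigma, smooth_fwhm_mm = smooth_fwhm_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# grid-centred affine: voxel centres, world origin at the grid centre
.phantom_affine <- function(dims, spacing) {
  aff <- diag(4)
  aff[1, 1] <- spacing[1]; aff[2, 2] <- spacing[2]; aff[3, 3] <- spacing[3]
  aff[1:3, 4] <- -spacing * (dims - 1) / 2
  aff
}

# set vox[d <= radius] <- hu for the cylinder around segment p0-p1,
# restricted to the segment's padded bounding box
.fill_cylinder <- function(vox, affine, p0, p1, radius, hu) {
  dims <- dim(vox)
  inv <- solve(affine)
  pad <- radius + max(sqrt(colSums(affine[1:3, 1:3]^2)))
  lo <- pmin(p0, p1) - pad
  hi <- pmax(p0, p1) + pad
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  ci <- cbind(corners, 1) %*% t(inv[1:3, , drop = FALSE])
  i0 <- pmax(floor(apply(ci, 2, min)), 0)
  i1 <- pmin(ceiling(apply(ci, 2, max)), dims - 1)
  if (any(i0 > i1)) return(vox)
  idx <- as.matrix(expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2],
                               k = i0[3]:i1[3]))
  w <- cbind(idx, 1) %*% t(affine[1:3, , drop = FALSE])
  u <- p1 - p0
  len2 <- sum(u^2)
  d0 <- sweep(w, 2, p0)
  tt <- pmin(pmax((d0 %*% u) / len2, 0), 1)
  dist2 <- rowSums((d0 - tt %*% t(u))^2)
  sel <- dist2 <= radius^2
  if (any(sel)) vox[idx[sel, , drop = FALSE] + 1] <- hu
  vox
}

# separable Gaussian smoothing along each axis (partial-volume realism
# option), implemented as shift-and-add with edge replication
.smooth_volume <- function(vox, sigma_vox) {
  d <- dim(vox)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-((-half:half)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    n <- d[axis]
    acc <- array(0, d)
    for (t in -half:half) {
      # source index along `axis`, clamped at the edges
      src <- pmin(pmax(seq_len(n) + t, 1L), n)
      shifted <- switch(axis,
                        vox[src, , , drop = FALSE],
                        vox[, src, , drop = FALSE],
                        vox[, , src, drop = FALSE])
      acc <- acc + kern[t + half + 1] * shifted
    }
    vox <- acc
  }
  vox
}

#' Generate a synthetic frame-CT phantom with ground truth
#'
#' Builds the HU volume described by `cfg` (air at -1000 HU, head ellipsoid,
#' optional skull shell, six localizer rods at the posed plate positions) and
#' returns it with the ground truth needed by validation: the posed vertex
#' positions, the pose itself, and the volume geometry.
#'
#' @param cfg A [phantom_config()].
#' @return List with `volume` (a [ct_volume()]) and `truth` (class
#'   `phantom_truth`): `vertices` (4 x 3 posed RAS, rows LA/RA/LP/RP),
#'   `vertex_bottoms`, `pose`, `marker_center` (NULL until
#'   [embed_target_marker()] is used), `affine`, `dims`, `spacing`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  dims <- cfg$dims; spacing <- cfg$spacing
  aff <- .phantom_affine(dims, spacing)
  ref <- reference_vertices(cfg$frame)
  h <- cfg$frame$fiducial_height
  tops <- ref$ras
  bottoms <- sweep(tops, 2, c(0, 0, h))
  posed_tops <- apply_transform(cfg$pose, tops)
  posed_bottoms <- apply_transform(cfg$pose, bottoms)
  rownames(posed_tops) <- rownames(posed_bottoms) <- rownames(tops)

  # field-of-view check: every rod endpoint must lie inside the grid (the
  # cylinder rasterizer clips a rod surface that merely grazes the boundary)
  world_lo <- aff[1:3, 4]
  world_hi <- aff[1:3, 4] + spacing * (dims - 1)
  ends <- rbind(posed_tops, posed_bottoms)
  if (any(sweep(ends, 2, world_lo, "<")) ||
      any(sweep(ends, 2, world_hi, ">")))
    stop("generate_phantom: posed localizer plates exceed the field of view",
         call. = FALSE)

  vox <- array(-1000, dim = dims)

  # head ellipsoid (+ optional skull shell), evaluated slice by slice in
  # frame coordinates so the head is posed together with the frame; work is
  # restricted to the exact bounding box of the posed outer ellipsoid
  R <- cfg$pose$rotation; tr <- cfg$pose$translation
  sa_in <- cfg$head_semiaxes
  sa_out <- sa_in + if (cfg$skull) cfg$skull_thickness else 0
  half_ext <- sqrt((R^2) %*% (sa_out^2))  # world half-extent per axis
  inv <- solve(aff)
  corners <- as.matrix(expand.grid(tr[1] + c(-1, 1) * half_ext[1],
                                   tr[2] + c(-1, 1) * half_ext[2],
                                   tr[3] + c(-1, 1) * half_ext[3]))
  ci <- cbind(corners, 1) %*% t(inv[1:3, , drop = FALSE])
  b0 <- pmax(floor(apply(ci, 2, min)), 0)
  b1 <- pmin(ceiling(apply(ci, 2, max)), dims - 1)
  if (all(b0 <= b1)) {
    ii <- b0[1]:b1[1]; jj <- b0[2]:b1[2]
    ij <- cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
    base <- ij %*% t(aff[1:3, 1:2])
    for (k in b0[3]:b1[3]) {
      w <- sweep(base, 2, aff[1:3, 3] * k + aff[1:3, 4], "+")
      xf <- sweep(w, 2, tr) %*% R   # == t(R) %*% (w - tr), rowwise
      q_out <- (xf[, 1] / sa_out[1])^2 + (xf[, 2] / sa_out[2])^2 +
        (xf[, 3] / sa_out[3])^2
      q_in <- (xf[, 1] / sa_in[1])^2 + (xf[, 2] / sa_in[2])^2 +
        (xf[, 3] / sa_in[3])^2
      sl <- vox[ii + 1, jj + 1, k + 1]
      if (cfg$skull) sl[q_out <= 1] <- cfg$skull_hu
      sl[q_in <= 1] <- cfg$tissue_hu
      vox[ii + 1, jj + 1, k + 1] <- sl
    }
  }

  # localizer rods: two verticals and one diagonal per plate
  for (side in c("L", "R")) {
    ant <- paste0(side, "A"); post <- paste0(side, "P")
    segs <- list(rbind(posed_tops[ant, ], posed_bottoms[ant, ]),
                 rbind(posed_tops[post, ], posed_bottoms[post, ]),
                 rbind(posed_bottoms[post, ], posed_tops[ant, ]))
    for (s in segs)
      vox <- .fill_cylinder(vox, aff, s[1, ], s[2, ], cfg$rod_radius,
                            cfg$rod_hu)
  }

  if (cfg$smooth_fwhm_mm > 0) {
    sigma_vox <- (cfg$smooth_fwhm_mm / 2.3548) / spacing
    vox <- .smooth_volume(vox, sigma_vox)
  }
  if (cfg$noise_sigma > 0) {
    vox <- vox + .with_seed(cfg$rng_seed,
                            array(stats::rnorm(prod(dims), 0,
                                               cfg$noise_sigma), dims))
  }

  truth <- structure(list(vertices = posed_tops,
                          vertex_bottoms = posed_bottoms,
                          pose = cfg$pose,
                          marker_center = NULL,
                          affine = aff, dims = dims, spacing = spacing),
                     class = "phantom_truth")
  list(volume = ct_volume(vox, aff), truth = truth)
}

#' Embed a spherical target marker in a volume
#'
#' Sets every voxel whose centre lies within `diameter / 2` of `center` to
#' `hu` (default: a 5 mm sphere at 1200 HU, the voxel-filling convention used
#' to mark targets unambiguously for planning). All other voxels are
#' untouched.
#'
#' @param v A [ct_volume()].
#' @param center Sphere centre, RAS mm.
#' @param diameter Sphere diameter, mm (0 is a no-op).
#' @param hu Fill intensity, HU.
#' @return The modified [ct_volume()].
#' @export
embed_target_marker <- function(v, center, diameter = 5, hu = 1200) {
  stopifnot(inherits(v, "ct_volume"), diameter >= 0)
  center <- as.numeric(.as_points(center, "marker centre")[1, ])
  if (diameter == 0) return(v)
  r <- diameter / 2
  aff <- v$affine
  world_lo <- ras_from_voxel(v, c(0, 0, 0))
  world_hi <- ras_from_voxel(v, v$dims - 1)
  lo <- pmin(world_lo, world_hi); hi <- pmax(world_lo, world_hi)
  if (any(center - r < lo) || any(center + r > hi))
    stop("embed_target_marker: sphere extends outside the volume",
         call. = FALSE)
  inv <- solve(aff)
  pad <- r + max(v$spacing)
  corners <- as.matrix(expand.grid(center[1] + c(-pad, pad),
                                   center[2] + c(-pad, pad),
                                   center[3] + c(-pad, pad)))
  ci <- cbind(corners, 1) %*% t(inv[1:3, , drop = FALSE])
  i0 <- pmax(floor(apply(ci, 2, min)), 0)
  i1 <- pmin(ceiling(apply(ci, 2, max)), v$dims - 1)
  idx <- as.matrix(expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2],
                               k = i0[3]:i1[3]))
  w <- cbind(idx, 1) %*% t(aff[1:3, , drop = FALSE])
  sel <- rowSums(sweep(w, 2, center)^2) <= r^2
  if (any(sel)) v$voxels[idx[sel, , drop = FALSE] + 1] <- hu
  v
}

#' Perturbed seed sets for seed-sensitivity experiments
#'
#' Emulates variable manual seed placement: picks the axial slice nearest the
#' mid-height of the posed vertical rods, computes where each rod crosses
#' that slice, and displaces each of the four in-plane positions by an
#' integer offset drawn uniformly from the square of Chebyshev radius
#' `max_offset` voxels. Reproducible under `rng_seed`.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param n_sets Number of seed sets.
#' @param max_offset Maximum in-plane displacement, voxels (keep at or below
#'   the tracking radius).
#' @param rng_seed Seed for the displacement generator.
#' @return List of `n_sets` matrices, each 4 x 3 with 0-based columns
#'   `i`, `j`, `k`.
#' @export
perturb_seeds <- function(truth, n_sets = 5, max_offset = 7, rng_seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"), n_sets >= 1, max_offset >= 0)
  aff <- truth$affine
  inv <- solve(aff)
  tops <- truth$vertices
  bottoms <- truth$vertex_bottoms
  s_mid <- mean((tops[, 3] + bottoms[, 3]) / 2)
  # slice index whose world S is nearest the rod mid-height
  k_mid <- .round_half_away((s_mid - aff[3, 4]) / aff[3, 3])
  k_mid <- min(max(k_mid, 0), truth$dims[3] - 1)
  s_k <- aff[3, 3] * k_mid + aff[3, 4]
  base <- matrix(0, 4, 3, dimnames = list(rownames(tops), c("i", "j", "k")))
  for (r in 1:4) {
    tt <- (s_k - tops[r, 3]) / (bottoms[r, 3] - tops[r, 3])
    p <- tops[r, ] + tt * (bottoms[r, ] - tops[r, ])
    idx <- .round_half_away(as.numeric(inv[1:3, ] %*% c(p, 1)))
    base[r, ] <- c(idx[1], idx[2], k_mid)
  }
  .with_seed(rng_seed, {
    lapply(seq_len(n_sets), function(s) {
      off <- if (max_offset == 0) matrix(0, 4, 2) else
        matrix(sample(seq(-max_offset, max_offset), 8, replace = TRUE), 4, 2)
      out <- base
      out[, 1:2] <- out[, 1:2] + off
      out[, 1] <- pmin(pmax(out[, 1], 0), truth$dims[1] - 1)
      out[, 2] <- pmin(pmax(out[, 2], 0), truth$dims[2] - 1)
      out
    })
  })
}

#' Write phantom ground truth as JSON
#'
#' @param truth A `phantom_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(list(
    vertices = apply(truth$vertices, 1, as.list, simplify = FALSE),
    pose = transform_matrix(truth$pose),
    marker_center = truth$marker_center,
    spacing = truth$spacing, dims = truth$dims),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
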