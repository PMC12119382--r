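# Layerwise max-intensity tracking (LMIT): refine rough user seeds to the
# localizer-rod maxima, then follow each rod upward slice by slice until the
# intensity drops below threshold; the last position is the rod vertex.

# superior direction along the slice axis: +1 if increasing k increases S
.superior_step <- function(v) {
  sk <- v$affine[3, 3]
  if (abs(sk) < 1e-9)
    stop("volume slice axis is perpendicular to the S axis; cannot track",
         call. = FALSE)
  if (sk > 0) 1L else -1L
}

# in-plane window of Chebyshev radius `radius` around (i, j) on slice k,
# clipped at the borders; returns argmax with ties broken by smallest i,
# then smallest j (indices 0-based)
.window_argmax <- function(v, i, j, k, radius) {
  i0 <- max(0L, i - radius); i1 <- min(v$dims[1] - 1L, i + radius)
  j0 <- max(0L, j - radius); j1 <- min(v$dims[2] - 1L, j + radius)
  w <- v$voxels[(i0 + 1):(i1 + 1), (j0 + 1):(j1 + 1), k + 1, drop = FALSE]
  best <- which(w == max(w), arr.ind = TRUE)
  # column-major which() already orders by i fastest; first hit is the
  # smallest (j, i) pair -- reorder to smallest i, then j
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  c(i = unname(i0 + best[1, 1] - 1L), j = unname(j0 + best[1, 2] - 1L),
    max = unname(max(w)))
}

.seed_ijk <- function(seed) {
  s <- unlist(seed)
  if (!all(c("i", "j", "k") %in% names(s))) {
    if (length(s) != 3) stop("seed must have components i, j, k",
                             call. = FALSE)
    names(s) <- c("i", "j", "k")
  }
  stats::setNames(as.integer(round(s[c("i", "j", "k")])), c("i", "j", "k"))
}

#' Refine a rough seed to the in-plane intensity maximum
#'
#' Expands a square window of Chebyshev radius `radius` (default 10 voxels,
#' a 21 x 21 region) around the seed on its own axial slice and returns the
#' voxel with the highest HU value, so that rough manual clicks are corrected
#' onto the localizer rod. Ties are broken towards the smallest `i`, then
#' smallest `j`.
#'
#' @param v A [ct_volume()].
#' @param seed Named vector or list with 0-based components `i`, `j`
#'   (in-plane) and `k` (slice).
#' @param radius Window radius in voxels (>= 1).
#' @return 0-based voxel index, named numeric `(i, j, k)`.
#' @export
refine_seed <- function(v, seed, radius = 10) {
  stopifnot(inherits(v, "ct_volume"), radius >= 1)
  s <- .seed_ijk(seed)
  .check_index(v, matrix(as.numeric(s), 1))
  radius <- as.integer(radius)
  m <- .window_argmax(v, s[["i"]], s[["j"]], s[["k"]], radius)
  c(i = unname(m[["i"]]), j = unname(m[["j"]]), k = s[["k"]])
}

#' Track a localizer rod upward to its vertex
#'
#' Starting from a voxel on the rod, moves slice by slice towards the
#' patient's superior (the direction is derived from the volume affine, not
#' from slice order), at each slice searching the square window of radius
#' `radius` centred on the previous position for the maximum-HU voxel. The
#' walk stops when that window maximum drops below `threshold` HU or the
#' volume ends; the last accepted position is the rod vertex.
#'
#' @param v A [ct_volume()].
#' @param start 0-based voxel index `(i, j, k)` with HU >= `threshold`.
#' @param radius In-plane search radius in voxels.
#' @param threshold Termination threshold in HU (default 500).
#' @return An object of class `track_result`: list with `path` (m x 3 matrix
#'   of 0-based voxel indices, one row per visited slice), `vertex` (RAS mm),
#'   `terminated_by_threshold` and `peak_hu_at_vertex`.
#' @export
track_vertex <- function(v, start, radius = 10, threshold = 500) {
  stopifnot(inherits(v, "ct_volume"), radius >= 1)
  s <- .seed_ijk(start)
  .check_index(v, matrix(as.numeric(s), 1))
  if (hu_at(v, as.numeric(s)) < threshold)
    stop("track_vertex: seed rejected, HU below threshold (",
         hu_at(v, as.numeric(s)), " < ", threshold, ")", call. = FALSE)
  step <- .superior_step(v)
  radius <- as.integer(radius)
  cur <- s
  path <- matrix(as.numeric(s), 1, dimnames = list(NULL, c("i", "j", "k")))
  peak <- hu_at(v, as.numeric(s))
  terminated <- FALSE
  repeat {
    k_next <- cur[["k"]] + step
    if (k_next < 0 || k_next > v$dims[3] - 1) break
    m <- .window_argmax(v, cur[["i"]], cur[["j"]], k_next, radius)
    if (m[["max"]] < threshold) { terminated <- TRUE; break }
    cur <- c(i = as.integer(m[["i"]]), j = as.integer(m[["j"]]),
             k = as.integer(k_next))
    peak <- m[["max"]]
    path <- rbind(path, as.numeric(cur))
  }
  vertex <- ras_from_voxel(v, as.numeric(cur))
  structure(list(path = path, vertex = vertex,
                 terminated_by_threshold = terminated,
                 peak_hu_at_vertex = unname(peak)),
            class = "track_result")
}

#' Detect and label the four localizer vertices
#'
#' Runs [refine_seed()] then [track_vertex()] on each of four rough seeds
#' (order-free) and labels the resulting vertices by quadrant relative to
#' their RAS centroid: left/right by the R axis, anterior/posterior by the
#' A axis. Seeds refining to the same voxel, tracks terminating at the same
#' vertex, or vertices within 1 mm of a centroid axis (ambiguous quadrant)
#' raise errors prompting re-seeding.
#'
#' @param v A [ct_volume()].
#' @param seeds List of exactly 4 seeds (each with 0-based `i`, `j`, `k`) or
#'   a 4 x 3 matrix with columns i, j, k.
#' @param radius In-plane search radius in voxels.
#' @param threshold Termination threshold in HU.
#' @return An object of class `fiducial_set`: list with `ras` (4 x 3 matrix,
#'   rows LA, RA, LP, RP), `voxel` (matching 0-based indices) and `tracks`.
#' @export
detect_fiducials <- function(v, seeds, radius = 10, threshold = 500) {
  stopifnot(inherits(v, "ct_volume"))
  if (is.matrix(seeds))
    seeds <- lapply(seq_len(nrow(seeds)), function(r)
      c(i = seeds[r, 1], j = seeds[r, 2], k = seeds[r, 3]))
  if (length(seeds) != 4)
    stop("detect_fiducials: exactly 4 seeds are required, got ",
         length(seeds), call. = FALSE)
  refined <- t(vapply(seeds, function(s) refine_seed(v, s, radius),
                      numeric(3)))
  if (anyDuplicated(refined))
    stop("detect_fiducials: two seeds refined to the same voxel; ",
         "place one seed near each rod", call. = FALSE)
  tracks <- lapply(seq_len(4), function(r)
    track_vertex(v, refined[r, ], radius, threshold))
  vox <- t(vapply(tracks, function(tr)
    as.numeric(tr$path[nrow(tr$path), ]), numeric(3)))
  if (anyDuplicated(vox))
    stop("detect_fiducials: two tracks terminated at the same vertex; ",
         "re-seed on distinct rods", call. = FALSE)
  ras <- t(vapply(tracks, function(tr) tr$vertex, numeric(3)))
  centroid <- colMeans(ras)
  dr <- ras[, 1] - centroid[1]
  da <- ras[, 2] - centroid[2]
  if (any(abs(dr) < 1) || any(abs(da) < 1))
    stop("detect_fiducials: ambiguous quadrant assignment (vertex within ",
         "1 mm of a centroid axis); re-seed", call. = FALSE)
  labels <- paste0(ifelse(dr < 0, "L", "R"), ifelse(da > 0, "A", "P"))
  if (anyDuplicated(labels))
    stop("detect_fiducials: quadrant labelling failed (two vertices in the ",
         "same quadrant); re-seed", call. = FALSE)
  ord <- match(c("LA", "RA", "LP", "RP"), labels)
  ras <- ras[ord, , drop = FALSE]
  vox <- vox[ord, , drop = FALSE]
  dimnames(ras) <- list(c("LA", "RA", "LP", "RP"), c("r", "a", "s"))
  dimnames(vox) <- list(c("LA", "RA", "LP", "RP"), c("i", "j", "k"))
  structure(list(ras = ras, voxel = vox, tracks = tracks[ord]),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat("Detected fiducial vertices (RAS mm):\n")
  print(round(x$ras, 3))
  invisible(x)
}

#' Read seeds from a CSV or JSON file
#'
#' CSV files need columns `k`, `i`, `j` (0-based voxel indices, one seed per
#' row); JSON files hold an array of objects with the same keys.
#'
#' @param path Seed file (`.csv` or `.json`).
#' @return List of seeds suitable for [detect_fiducials()].
#' @export
read_seeds <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  if (!all(c("k", "i", "j") %in% names(df)))
    stop("seed file must have columns k, i, j", call. = FALSE)
  lapply(seq_len(nrow(df)), function(r)
    c(i = df$i[r], j = df$j[r], k = df$k[r]))
}

#' Write seeds to CSV
#'
#' @param seeds List of seeds (named `i`, `j`, `k`) or a matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  if (is.matrix(seeds))
    seeds <- lapply(seq_len(nrow(seeds)), function(r)
      c(i = seeds[r, 1], j = seeds[r, 2], k = seeds[r, 3]))
  df <- do.call(rbind, lapply(seeds, function(s)
    data.frame(k = s[["k"]], i = s[["i"]], j = s[["j"]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a detected fiducial set as CSV or JSON
#'
#' @param fids A `fiducial_set` from [detect_fiducials()].
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fids, path) {
  stopifnot(inherits(fids, "fiducial_set"))
  df <- data.frame(label = rownames(fids$ras),
                   r = fids$ras[, 1], a = fids$ras[, 2], s = fids$ras[, 3],
                   row.names = NULL)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a fiducial set written by [write_fiducials()]
#'
#' @param path `.csv` or `.json` file with columns label, r, a, s.
#' @return A `fiducial_set` (without track information).
#' @export
read_fiducials <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  ras <- as.matrix(df[, c("r", "a", "s")])
  rownames(ras) <- df$label
  structure(list(ras = ras, voxel = NULL, tracks = NULL),
            class = "fiducial_set")
}
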