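#' CT volume container
#'
#' Holds a 3-D grid of Hounsfield-unit values together with its voxel spacing
#' and a 4 x 4 affine mapping 0-based voxel indices (i, j, k) to RAS world
#' coordinates in mm. World coordinates refer to voxel centres. The third
#' array axis indexes axial slices.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param affine 4 x 4 voxel-index -> RAS-mm matrix (0-based indices, voxel
#'   centre convention).
#' @return An object of class `ct_volume` with fields `voxels`, `affine`,
#'   `spacing` (mm per axis, from the affine column norms) and `dims`.
#' @export
ct_volume <- function(voxels, affine) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4, 4)))
  dims <- dim(voxels)
  if (any(dims < 2))
    stop("ct_volume: each axis must have at least 2 voxels", call. = FALSE)
  A <- affine[1:3, 1:3]
  if (!all(is.finite(affine)) || abs(det(A)) < 1e-12)
    stop("ct_volume: affine must be finite with nonsingular 3x3 part",
         call. = FALSE)
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0))
    stop("ct_volume: spacing must be positive on every axis", call. = FALSE)
  structure(list(voxels = voxels, affine = affine, spacing = spacing,
                 dims = as.integer(dims)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range: [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Load a CT volume from NIfTI or a DICOM series directory
#'
#' A file path is read as NIfTI (`.nii` / `.nii.gz`, sform preferred over
#' qform); a directory is read as a single DICOM series. DICOM patient (LPS)
#' coordinates are converted to RAS by negating the first two world axes, and
#' slices are sorted by position along the slice normal. A directory holding
#' more than one series is rejected, as is non-uniform slice spacing beyond
#' 1% of the median gap.
#'
#' @param path NIfTI file or DICOM series directory.
#' @return A [ct_volume()].
#' @export
load_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path))
    stop("load_volume: no such file or directory: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- unname(structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                          code = NULL, imagedim = NULL))
  aff <- matrix(as.numeric(aff), 4, 4)
  vox <- array(as.numeric(img), dim = dim(img))
  ct_volume(vox, aff)
}

#' Write a CT volume as NIfTI
#'
#' @param v A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "ct_volume"))
  img <- RNifti::asNifti(v$voxels)
  RNifti::pixdim(img) <- v$spacing
  RNifti::sform(img) <- structure(v$affine, code = 2L)
  RNifti::qform(img) <- structure(v$affine, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

.check_index <- function(v, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  if (any(!is.finite(idx)) || any(idx != round(idx)))
    stop("voxel index must be integer-valued", call. = FALSE)
  if (any(idx < 0) || any(sweep(idx, 2, v$dims - 1, ">") ))
    stop("voxel index out of bounds", call. = FALSE)
  idx
}

#' Map voxel indices to RAS world coordinates
#'
#' Applies the volume affine to 0-based indices `(i, j, k, 1)`; world
#' coordinates are voxel centres.
#'
#' @param v A [ct_volume()].
#' @param idx Numeric length 3 `(i, j, k)` (0-based) or an n x 3 matrix.
#' @return RAS coordinates (mm), same shape as `idx`.
#' @export
ras_from_voxel <- function(v, idx) {
  stopifnot(inherits(v, "ct_volume"))
  m <- .as_points(idx, "voxel index")
  m2 <- .check_index(v, m)
  out <- cbind(m2, 1) %*% t(v$affine[1:3, , drop = FALSE])
  colnames(out) <- c("r", "a", "s")
  .restore_shape(out, m)
}

# round half away from zero, per axis
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map RAS world coordinates to the nearest voxel index
#'
#' Applies the inverse affine and rounds each axis half away from zero.
#'
#' @param v A [ct_volume()].
#' @param p RAS point (length 3) or n x 3 matrix, mm.
#' @return 0-based voxel indices, same shape as `p`; an error is raised if
#'   any rounded index falls outside the grid.
#' @export
voxel_from_ras <- function(v, p) {
  stopifnot(inherits(v, "ct_volume"))
  m <- .as_points(p, "RAS point")
  inv <- solve(v$affine)
  cont <- cbind(m, 1) %*% t(inv[1:3, , drop = FALSE])
  idx <- .round_half_away(cont)
  if (any(idx < 0) || any(sweep(idx, 2, v$dims - 1, ">")))
    stop("voxel_from_ras: point maps outside the volume", call. = FALSE)
  colnames(idx) <- c("i", "j", "k")
  .restore_shape(idx, m)
}

#' HU value at a voxel index
#'
#' @param v A [ct_volume()].
#' @param idx 0-based voxel index, length 3 or n x 3 matrix.
#' @return HU value(s).
#' @export
hu_at <- function(v, idx) {
  stopifnot(inherits(v, "ct_volume"))
  m <- .as_points(idx, "voxel index")
  m <- .check_index(v, m)
  v$voxels[m + 1]
}

#' Resample a volume under a rigid transform
#'
#' Produces a volume on the same grid whose value at world position `x` is
#' the trilinear interpolation of the input at `t^{-1}(x)`; positions mapping
#' outside the input field of view are filled with -1024 HU (air). Planning
#' itself only transforms coordinates; resampling is provided for
#' visualization of the registered volume.
#'
#' @param v A [ct_volume()].
#' @param t A [rigid_transform()] (e.g. a frame registration transform).
#' @param fill Fill value for out-of-field positions, default -1024.
#' @return A [ct_volume()] on the same grid.
#' @export
resample_rigid <- function(v, t, fill = -1024) {
  stopifnot(inherits(v, "ct_volume"), inherits(t, "rigid_transform"))
  tinv <- invert_transform(t)
  dims <- v$dims
  # all voxel centres of the output grid, in world coordinates
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  world <- cbind(idx, 1) %*% t(v$affine[1:3, , drop = FALSE])
  src_world <- sweep(world %*% t(tinv$rotation), 2, tinv$translation, "+")
  inv <- solve(v$affine)
  src <- cbind(src_world, 1) %*% t(inv[1:3, , drop = FALSE])
  out <- .trilinear(v$voxels, src, fill)
  ct_volume(array(out, dim = dims), v$affine)
}

# trilinear interpolation at continuous 0-based voxel coordinates (n x 3)
.trilinear <- function(vox, src, fill) {
  dims <- dim(vox)
  i0 <- floor(src[, 1]); j0 <- floor(src[, 2]); k0 <- floor(src[, 3])
  fi <- src[, 1] - i0; fj <- src[, 2] - j0; fk <- src[, 3] - k0
  # allow exact landing on the far boundary
  hi_i <- src[, 1] == dims[1] - 1; hi_j <- src[, 2] == dims[2] - 1
  hi_k <- src[, 3] == dims[3] - 1
  i0[hi_i] <- dims[1] - 2; fi[hi_i] <- 1
  j0[hi_j] <- dims[2] - 2; fj[hi_j] <- 1
  k0[hi_k] <- dims[3] - 2; fk[hi_k] <- 1
  inside <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    i0 <= dims[1] - 2 & j0 <= dims[2] - 2 & k0 <= dims[3] - 2
  out <- rep(fill, nrow(src))
  if (!any(inside)) return(out)
  i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
  fi <- fi[inside]; fj <- fj[inside]; fk <- fk[inside]
  at <- function(di, dj, dk)
    vox[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  val <-
    at(0, 0, 0) * (1 - fi) * (1 - fj) * (1 - fk) +
    at(1, 0, 0) * fi * (1 - fj) * (1 - fk) +
    at(0, 1, 0) * (1 - fi) * fj * (1 - fk) +
    at(0, 0, 1) * (1 - fi) * (1 - fj) * fk +
    at(1, 1, 0) * fi * fj * (1 - fk) +
    at(1, 0, 1) * fi * (1 - fj) * fk +
    at(0, 1, 1) * (1 - fi) * fj * fk +
    at(1, 1, 1) * fi * fj * fk
  out[inside] <- val
  out
}
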