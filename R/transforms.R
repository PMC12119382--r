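#' Rigid transform in 3-D
#'
#' A proper rigid transform `p -> R p + t`: a rotation matrix (orthonormal,
#' determinant +1) plus a translation in mm. Used to map detected frame space
#' to the canonical frame space and to pose phantoms.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Numeric length 3, mm.
#' @param tol Tolerance on orthonormality and determinant.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)))
    stop("rigid_transform: non-finite components", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rigid_transform: rotation is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > tol)
    stop("rigid_transform: rotation must be proper (det = +1)", call. = FALSE)
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (p -> R p + t)\n  rotation:\n")
  print(round(x$rotation, 6))
  cat(sprintf("  translation: (%.4f, %.4f, %.4f) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation from Euler angles
#'
#' Intrinsic rotations about the fixed R, A and S axes applied in the order
#' S (yaw), then A, then R, i.e. `R = Rx(rx) %*% Ry(ry) %*% Rz(rz)` with
#' right-handed positive angles in degrees.
#'
#' @param rx,ry,rz Rotation angles about the first, second and third axes,
#'   degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_euler <- function(rx = 0, ry = 0, rz = 0) {
  d <- pi / 180
  cx <- cos(rx * d); sx <- sin(rx * d)
  cy <- cos(ry * d); sy <- sin(ry * d)
  cz <- cos(rz * d); sz <- sin(rz * d)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Apply a rigid transform to points
#'
#' @param t A [rigid_transform()].
#' @param p Numeric length 3 or n x 3 matrix of points (mm).
#' @return Transformed points, same shape as `p`.
#' @export
apply_transform <- function(t, p) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- .as_points(p)
  out <- m %*% t(t$rotation)
  out <- sweep(out, 2, t$translation, "+")
  colnames(out) <- colnames(m)
  .restore_shape(out, m)
}

#' Invert or compose rigid transforms
#'
#' `invert_transform(t)` returns the transform mapping back, and
#' `compose_transform(a, b)` the transform applying `b` first and then `a`.
#'
#' @param t,a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation), tol = 1e-6)
}

#' @rdname invert_transform
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  tol = 1e-6)
}

#' Homogeneous 4 x 4 matrix of a rigid transform
#'
#' @param t A [rigid_transform()].
#' @return 4 x 4 matrix.
#' @export
transform_matrix <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- t$rotation
  m[1:3, 4] <- t$translation
  m
}

#' Write a rigid transform to a plain-text file
#'
#' Writes the homogeneous 4 x 4 matrix, one row per line, space separated.
#' With `format = "itk"` an ITK-style `MatrixOffsetTransformBase` text file is
#' written instead (row-major 3 x 3 parameters followed by the offset).
#'
#' @param t A [rigid_transform()].
#' @param path Output path.
#' @param format `"matrix"` (default) or `"itk"`.
#' @return `path`, invisibly.
#' @export
write_transform <- function(t, path, format = c("matrix", "itk")) {
  format <- match.arg(format)
  if (format == "matrix") {
    m <- transform_matrix(t)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.12g", r),
                                             collapse = " ")), path)
  } else {
    pars <- c(t(t$rotation))  # row-major
    writeLines(c("#Insight Transform File V1.0",
                 "#Transform 0",
                 "Transform: MatrixOffsetTransformBase_double_3_3",
                 paste("Parameters:", paste(sprintf("%.12g",
                       c(pars, t$translation)), collapse = " ")),
                 "FixedParameters: 0 0 0"), path)
  }
  invisible(path)
}

#' Read a rigid transform written by [write_transform()]
#'
#' @param path Path to a plain-text 4 x 4 matrix file.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  rows <- lapply(readLines(path)[1:4],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  rigid_transform(m[1:3, 1:3], m[1:3, 4], tol = 1e-6)
}
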