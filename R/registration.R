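#' Optimal rigid alignment of paired point sets (Kabsch algorithm)
#'
#' Computes the proper rigid transform minimizing the root-mean-square
#' distance between `apply_transform(t, source)` and `target`: centroids are
#' subtracted, the cross-covariance is decomposed by SVD, and the sign of the
#' smallest singular direction is corrected so the rotation has determinant
#' +1 (no reflection is ever returned, even for reflected input).
#'
#' @param source n x 3 matrix of points (n >= 3, not collinear), mm.
#' @param target n x 3 matrix of matching points, mm.
#' @return A [rigid_transform()] mapping `source` onto `target` in the
#'   least-squares sense.
#' @references Kabsch, W. (1976) A solution for the best rotation to relate
#'   two sets of vectors. Acta Crystallographica A32, 922-923.
#' @export
kabsch_transform <- function(source, target) {
  source <- .as_points(source, "source")
  target <- .as_points(target, "target")
  if (nrow(source) != nrow(target))
    stop("kabsch_transform: source and target must have equal counts",
         call. = FALSE)
  if (nrow(source) < 3)
    stop("kabsch_transform: at least 3 point pairs are required",
         call. = FALSE)
  cs <- colMeans(source)
  ct <- colMeans(target)
  sc <- sweep(source, 2, cs)
  tc <- sweep(target, 2, ct)
  # collinear (or coincident) source points leave the rotation about the
  # line undetermined
  sv <- svd(sc, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("kabsch_transform: degenerate (collinear) point configuration",
         call. = FALSE)
  H <- crossprod(sc, tc)           # sum over i of p_i q_i^T
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  if (d == 0) d <- 1
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  rigid_transform(R, as.numeric(ct - R %*% cs), tol = 1e-6)
}

#' Register detected fiducials to the canonical frame position
#'
#' Pairs the detected vertex of each N-localizer rod with the canonical
#' reference vertex of the same label (LA/RA/LP/RP), computes the optimal
#' rigid transform with [kabsch_transform()], and reports per-fiducial
#' residuals and their RMSE (the fiducial registration error). A warning flag
#' is set when the RMSE exceeds `spec$rmse_warning` (default 1 mm), the level
#' at which re-seeding should be considered.
#'
#' @param detected A `fiducial_set` (see [detect_fiducials()]) or a 4 x 3
#'   matrix of RAS points with rownames LA, RA, LP, RP.
#' @param spec A [frame_spec()].
#' @return An object of class `registration_result`: list with `transform`
#'   (detected frame space -> canonical frame space),
#'   `per_fiducial_residual_mm` (named length 4), `rmse_mm` and `warning`.
#' @export
register_frame <- function(detected, spec = frame_spec()) {
  pts <- if (inherits(detected, "fiducial_set")) detected$ras else detected
  pts <- as.matrix(pts)
  ref <- reference_vertices(spec)
  if (is.null(rownames(pts)) || !setequal(rownames(pts), ref$labels) ||
      anyDuplicated(rownames(pts)))
    stop("register_frame: detected labels must match reference labels ",
         "(LA, RA, LP, RP)", call. = FALSE)
  pts <- pts[ref$labels, , drop = FALSE]
  t <- kabsch_transform(pts, ref$ras)
  mapped <- apply_transform(t, pts)
  res <- sqrt(rowSums((mapped - ref$ras)^2))
  names(res) <- ref$labels
  rmse <- sqrt(mean(res^2))
  structure(list(transform = t,
                 per_fiducial_residual_mm = res,
                 rmse_mm = rmse,
                 warning = rmse > spec$rmse_warning),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("Frame registration\n")
  cat(sprintf("  RMSE: %.3f mm%s\n", x$rmse_mm,
              if (x$warning) "  ** above warning threshold **" else ""))
  cat("  per-fiducial residuals (mm):\n")
  print(round(x$per_fiducial_residual_mm, 3))
  invisible(x)
}

#' Write a registration result as JSON
#'
#' Emits the homogeneous transform matrix, per-fiducial residuals, RMSE and
#' the warning flag.
#'
#' @param reg A `registration_result` from [register_frame()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_registration_json <- function(reg, path) {
  stopifnot(inherits(reg, "registration_result"))
  jsonlite::write_json(list(
    matrix = transform_matrix(reg$transform),
    per_fiducial_residual_mm = as.list(reg$per_fiducial_residual_mm),
    rmse_mm = reg$rmse_mm,
    warning = reg$warning), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
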