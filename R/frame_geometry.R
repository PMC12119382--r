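#' Leksell frame specification
#'
#' Describes the geometry of a Leksell-type stereotactic frame: the distance
#' between the two lateral N-localizer plates, the width and height of each
#' plate, and the frame centre in frame (Leksell) coordinates. The Leksell
#' coordinate system has its origin at the superior posterior right corner of
#' the frame space, so all coordinates are positive over the head; the centre
#' defaults to (100, 100, 100) mm.
#'
#' @param plate_separation Distance between the two N-plates in mm.
#' @param fiducial_width Width of each N-plate in mm.
#' @param fiducial_height Height of each N-plate in mm.
#' @param center Frame centre in Leksell coordinates, numeric length 3 (mm).
#' @param rmse_warning Registration RMSE (mm) above which a warning is raised.
#' @return An object of class `frame_spec`.
#' @examples
#' spec <- frame_spec()
#' reference_vertices(spec)
#' @export
frame_spec <- function(plate_separation = 190, fiducial_width = 120,
                       fiducial_height = 120, center = c(100, 100, 100),
                       rmse_warning = 1.0) {
  stopifnot(is.numeric(plate_separation), length(plate_separation) == 1,
            is.numeric(fiducial_width), length(fiducial_width) == 1,
            is.numeric(fiducial_height), length(fiducial_height) == 1,
            is.numeric(center), length(center) == 3,
            is.numeric(rmse_warning), length(rmse_warning) == 1)
  if (!all(is.finite(c(plate_separation, fiducial_width, fiducial_height,
                       center, rmse_warning))))
    stop("frame_spec: all parameters must be finite", call. = FALSE)
  if (plate_separation <= 0 || fiducial_width <= 0 || fiducial_height <= 0)
    stop("frame_spec: separation, width and height must be positive",
         call. = FALSE)
  if (rmse_warning <= 0)
    stop("frame_spec: rmse_warning must be positive", call. = FALSE)
  structure(list(plate_separation = as.numeric(plate_separation),
                 fiducial_width = as.numeric(fiducial_width),
                 fiducial_height = as.numeric(fiducial_height),
                 center = as.numeric(center),
                 rmse_warning = as.numeric(rmse_warning)),
            class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat("Leksell frame specification\n")
  cat(sprintf("  plate separation : %g mm\n", x$plate_separation))
  cat(sprintf("  fiducial width   : %g mm\n", x$fiducial_width))
  cat(sprintf("  fiducial height  : %g mm\n", x$fiducial_height))
  cat(sprintf("  centre (Leksell) : (%g, %g, %g) mm\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  RMSE warning     : %g mm\n", x$rmse_warning))
  invisible(x)
}

# Accept a length-3 vector or an n x 3 matrix of points; return n x 3 matrix
# plus a flag so callers can hand back the original shape.
.as_points <- function(p, what = "point") {
  if (is.null(dim(p))) {
    if (length(p) != 3)
      stop(sprintf("%s must have 3 components", what), call. = FALSE)
    p <- matrix(as.numeric(p), nrow = 1)
    attr(p, "was_vector") <- TRUE
  } else {
    if (ncol(p) != 3)
      stop(sprintf("%s matrix must have 3 columns", what), call. = FALSE)
    p <- matrix(as.numeric(p), ncol = 3, dimnames = dimnames(p))
    attr(p, "was_vector") <- FALSE
  }
  if (!all(is.finite(p)))
    stop(sprintf("%s has non-finite components", what), call. = FALSE)
  p
}

.restore_shape <- function(m, template) {
  if (isTRUE(attr(template, "was_vector"))) as.numeric(m[1, ]) else {
    attr(m, "was_vector") <- NULL
    m
  }
}

#' Convert RAS image coordinates to Leksell frame coordinates
#'
#' After frame registration the frame centre sits at the RAS origin, the
#' Leksell X axis is anti-parallel to R, Y is parallel to A and Z is
#' anti-parallel to S. A point (R, A, S) therefore maps to
#' (cx - R, cy + A, cz - S) where (cx, cy, cz) is the frame centre,
#' (100 - R, 100 + A, 100 - S) for the standard frame.
#'
#' @param p RAS point, numeric length 3 `(r, a, s)` in mm, or an n x 3 matrix.
#' @param spec A [frame_spec()].
#' @return Leksell coordinates with the same shape as `p`.
#' @examples
#' leksell_from_ras(c(0, 0, 0))        # frame centre (100, 100, 100)
#' leksell_from_ras(c(-95, 60, 60))    # left anterior vertex (195, 160, 40)
#' @export
leksell_from_ras <- function(p, spec = frame_spec()) {
  stopifnot(inherits(spec, "frame_spec"))
  m <- .as_points(p, "RAS point")
  out <- cbind(spec$center[1] - m[, 1],
               spec$center[2] + m[, 2],
               spec$center[3] - m[, 3])
  colnames(out) <- c("x", "y", "z")
  .restore_shape(out, m)
}

#' Convert Leksell frame coordinates to RAS image coordinates
#'
#' Exact inverse of [leksell_from_ras()]: (X, Y, Z) maps to
#' (cx - X, Y - cy, cz - Z).
#'
#' @param p Leksell point, numeric length 3 `(x, y, z)` in mm, or n x 3 matrix.
#' @param spec A [frame_spec()].
#' @return RAS coordinates with the same shape as `p`.
#' @examples
#' ras_from_leksell(c(195, 160, 40))   # (-95, 60, 60)
#' ras_from_leksell(c(100, 100, 100))  # origin
#' @export
ras_from_leksell <- function(p, spec = frame_spec()) {
  stopifnot(inherits(spec, "frame_spec"))
  m <- .as_points(p, "Leksell point")
  out <- cbind(spec$center[1] - m[, 1],
               m[, 2] - spec$center[2],
               spec$center[3] - m[, 3])
  colnames(out) <- c("r", "a", "s")
  .restore_shape(out, m)
}

#' Canonical reference vertices of the N-localizer plates
#'
#' The four top vertices of the vertical localizer rods, labelled LA, RA, LP,
#' RP (left/right anterior/posterior), given both in Leksell frame coordinates
#' and as their RAS images after the canonical registration (frame centre at
#' the RAS origin). For the default frame these are (195, 160, 40),
#' (5, 160, 40), (195, 40, 40), (5, 40, 40) in Leksell coordinates and
#' (-95, 60, 60), (95, 60, 60), (-95, -60, 60), (95, -60, 60) in RAS.
#'
#' Vertices sit at the top of the vertical rods: the lowest Leksell Z
#' (equivalently the highest S), which is where upward intensity tracking
#' terminates.
#'
#' @param spec A [frame_spec()].
#' @return An object of class `reference_fiducials`: list with `labels`,
#'   a 4 x 3 `leksell` matrix and a 4 x 3 `ras` matrix (rows named by label).
#' @export
reference_vertices <- function(spec = frame_spec()) {
  cx <- spec$center[1]; cy <- spec$center[2]; cz <- spec$center[3]
  hs <- spec$plate_separation / 2
  hw <- spec$fiducial_width / 2
  hh <- spec$fiducial_height / 2
  lek <- rbind(LA = c(cx + hs, cy + hw, cz - hh),
               RA = c(cx - hs, cy + hw, cz - hh),
               LP = c(cx + hs, cy - hw, cz - hh),
               RP = c(cx - hs, cy - hw, cz - hh))
  colnames(lek) <- c("x", "y", "z")
  ras <- ras_from_leksell(lek, spec)
  rownames(ras) <- rownames(lek)
  structure(list(labels = rownames(lek), leksell = lek, ras = ras),
            class = "reference_fiducials")
}

#' @export
print.reference_fiducials <- function(x, ...) {
  cat("Reference fiducial vertices\n  Leksell (mm):\n")
  print(round(x$leksell, 3))
  cat("  RAS (mm):\n")
  print(round(x$ras, 3))
  invisible(x)
}

#' Wireframe model of the localizer geometry
#'
#' Builds a polyline model of the frame in RAS coordinates at the canonical
#' (registered) position: the rectangle joining the four reference vertices
#' plus, for each lateral N-plate, its two vertical rods and the diagonal rod
#' running from the bottom of the posterior rod to the top of the anterior
#' rod. Intended for export to external 3-D viewers.
#'
#' @param spec A [frame_spec()].
#' @return A list of 10 segments; each segment is a 2 x 3 matrix of RAS
#'   endpoints (mm), with a `name` attribute.
#' @export
frame_wireframe <- function(spec = frame_spec()) {
  rv <- reference_vertices(spec)
  v <- rv$ras
  h <- spec$fiducial_height
  seg <- function(p0, p1, name) {
    s <- rbind(p0, p1)
    dimnames(s) <- list(NULL, c("r", "a", "s"))
    attr(s, "name") <- name
    s
  }
  bottom <- function(lab) v[lab, ] - c(0, 0, h)
  segments <- list(
    seg(v["LA", ], v["RA", ], "rect_anterior"),
    seg(v["RA", ], v["RP", ], "rect_right"),
    seg(v["RP", ], v["LP", ], "rect_posterior"),
    seg(v["LP", ], v["LA", ], "rect_left"))
  for (side in c("L", "R")) {
    ant <- paste0(side, "A"); post <- paste0(side, "P")
    segments <- c(segments, list(
      seg(v[ant, ], bottom(ant), paste0("rod_", side, "_anterior")),
      seg(v[post, ], bottom(post), paste0("rod_", side, "_posterior")),
      seg(bottom(post), v[ant, ], paste0("rod_", side, "_diagonal"))))
  }
  segments
}

#' Write a wireframe to a Wavefront OBJ polyline file
#'
#' @param segments List of 2 x 3 segment matrices, as from
#'   [frame_wireframe()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wireframe_obj <- function(segments, path) {
  lines <- character(0)
  n <- 0L
  for (s in segments) {
    nm <- attr(s, "name")
    if (!is.null(nm)) lines <- c(lines, paste("o", nm))
    lines <- c(lines,
               sprintf("v %.6f %.6f %.6f", s[1, 1], s[1, 2], s[1, 3]),
               sprintf("v %.6f %.6f %.6f", s[2, 1], s[2, 2], s[2, 3]),
               sprintf("l %d %d", n + 1L, n + 2L))
    n <- n + 2L
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a frame specification as YAML or JSON
#'
#' Serialized keys are `plate_separation_mm`, `fiducial_width_mm`,
#' `fiducial_height_mm`, `center` and `rmse_warning_mm`. The format is chosen
#' from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param spec A [frame_spec()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_frame_spec` returns `path` invisibly; `read_frame_spec`
#'   returns a [frame_spec()].
#' @export
write_frame_spec <- function(spec, path) {
  stopifnot(inherits(spec, "frame_spec"))
  x <- list(plate_separation_mm = spec$plate_separation,
            fiducial_width_mm = spec$fiducial_width,
            fiducial_height_mm = spec$fiducial_height,
            center = spec$center,
            rmse_warning_mm = spec$rmse_warning)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported frame spec format: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_frame_spec
#' @export
read_frame_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported frame spec format: ", path, call. = FALSE)
  frame_spec(plate_separation = x$plate_separation_mm,
             fiducial_width = x$fiducial_width_mm,
             fiducial_height = x$fiducial_height_mm,
             center = unlist(x$center),
             rmse_warning = x$rmse_warning_mm)
}
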