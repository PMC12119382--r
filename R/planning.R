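# Trajectory planning: Leksell coordinates of the registered target plus the
# arc and ring angles of the target -> entry direction.

.traj_vector <- function(target, entry) {
  t <- .as_points(target, "target")
  e <- .as_points(entry, "entry")
  if (nrow(t) != 1 || nrow(e) != 1)
    stop("target and entry must be single points", call. = FALSE)
  v <- as.numeric(e[1, ] - t[1, ])
  if (sqrt(sum(v^2)) <= 1e-6)
    stop("degenerate trajectory: entry coincides with target", call. = FALSE)
  v
}

#' Arc angle of a trajectory
#'
#' The angle between the target-to-entry vector and the R (left-right) axis:
#' `acos((Er - Tr) / |entry - target|)`, in degrees, in the range 0-180.
#'
#' @param target,entry RAS points (length 3, mm), after frame registration.
#' @return Angle in degrees.
#' @export
arc_angle <- function(target, entry) {
  v <- .traj_vector(target, entry)
  abs(acos(v[1] / sqrt(sum(v^2)))) * 180 / pi
}

#' Ring angle of a trajectory
#'
#' The angle between the A (posterior-anterior) axis and the projection of
#' the target-to-entry vector onto the A-S plane:
#' `90 - atan2(Ea - Ta, Es - Ts)` in degrees, wrapped into [0, 180). The
#' two-argument arctangent makes the angle well defined over the whole plane;
#' on the half-plane `Es - Ts > 0` it coincides with the single-argument form
#' `90 - atan((Ea - Ta) / (Es - Ts))`.
#'
#' @param target,entry RAS points (length 3, mm), after frame registration.
#' @return Angle in degrees in [0, 180).
#' @export
ring_angle <- function(target, entry) {
  v <- .traj_vector(target, entry)
  if (sqrt(v[2]^2 + v[3]^2) <= 1e-6)
    stop("ring angle undefined: trajectory is parallel to the R axis",
         call. = FALSE)
  (90 - atan2(v[2], v[3]) * 180 / pi) %% 180
}

#' Plan a trajectory for a registered frame
#'
#' Maps the target and entry points (given in the scanner's RAS coordinates)
#' through the frame-registration transform, converts the registered target
#' to Leksell frame coordinates, and computes the arc and ring angles and the
#' trajectory length. Optional per-angle offsets (default 0) accommodate
#' frames whose physical angle markings differ from the geometric convention.
#'
#' @param target,entry RAS points (length 3, mm) in the scanner coordinates
#'   of the loaded volume.
#' @param reg A `registration_result` from [register_frame()].
#' @param spec A [frame_spec()].
#' @param arc_offset_deg,ring_offset_deg Additive angle offsets in degrees.
#' @return An object of class `trajectory_plan` with fields `target_ras`,
#'   `entry_ras` (registered coordinates), `target_leksell`, `arc_deg`,
#'   `ring_deg`, `trajectory_length_mm`, `rmse_mm` and `registration_warning`.
#' @export
plan_trajectory <- function(target, entry, reg, spec = frame_spec(),
                            arc_offset_deg = 0, ring_offset_deg = 0) {
  stopifnot(inherits(reg, "registration_result"),
            inherits(spec, "frame_spec"))
  t_reg <- apply_transform(reg$transform, as.numeric(target))
  e_reg <- apply_transform(reg$transform, as.numeric(entry))
  v <- .traj_vector(t_reg, e_reg)
  structure(list(
    target_ras = t_reg,
    entry_ras = e_reg,
    target_leksell = leksell_from_ras(t_reg, spec),
    arc_deg = arc_angle(t_reg, e_reg) + arc_offset_deg,
    ring_deg = ring_angle(t_reg, e_reg) + ring_offset_deg,
    trajectory_length_mm = sqrt(sum(v^2)),
    rmse_mm = reg$rmse_mm,
    registration_warning = reg$warning),
    class = "trajectory_plan")
}

#' @export
print.trajectory_plan <- function(x, ...) {
  # vernier resolution: 0.1 mm / 0.1 degree
  cat("Stereotactic trajectory plan\n")
  cat(sprintf("  Leksell target (X, Y, Z): (%.1f, %.1f, %.1f) mm\n",
              x$target_leksell[1], x$target_leksell[2], x$target_leksell[3]))
  cat(sprintf("  arc angle : %.1f deg\n", x$arc_deg))
  cat(sprintf("  ring angle: %.1f deg\n", x$ring_deg))
  cat(sprintf("  trajectory length: %.1f mm\n", x$trajectory_length_mm))
  cat(sprintf("  registration RMSE: %.2f mm%s\n", x$rmse_mm,
              if (x$registration_warning) "  ** warning **" else ""))
  invisible(x)
}

#' Export a plan as a JSON report plus an OBJ geometry file
#'
#' The report holds the Leksell coordinates, angles, trajectory length,
#' registration RMSE and warning flag; the geometry file contains the
#' trajectory segment followed by the frame wireframe, as OBJ polylines in
#' registered RAS coordinates.
#'
#' @param plan A [plan_trajectory()] result.
#' @param spec A [frame_spec()].
#' @param report_path Output JSON path.
#' @param geometry_path Output OBJ path.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_plan <- function(plan, spec = frame_spec(),
                        report_path = "plan.json",
                        geometry_path = "plan_geometry.obj") {
  stopifnot(inherits(plan, "trajectory_plan"))
  jsonlite::write_json(list(
    target_leksell = list(x = plan$target_leksell[[1]],
                          y = plan$target_leksell[[2]],
                          z = plan$target_leksell[[3]]),
    target_ras = as.list(stats::setNames(as.numeric(plan$target_ras),
                                         c("r", "a", "s"))),
    entry_ras = as.list(stats::setNames(as.numeric(plan$entry_ras),
                                        c("r", "a", "s"))),
    arc_deg = plan$arc_deg,
    ring_deg = plan$ring_deg,
    trajectory_length_mm = plan$trajectory_length_mm,
    rmse_mm = plan$rmse_mm,
    registration_warning = plan$registration_warning),
    report_path, auto_unbox = TRUE, digits = NA)
  traj <- rbind(as.numeric(plan$target_ras), as.numeric(plan$entry_ras))
  dimnames(traj) <- list(NULL, c("r", "a", "s"))
  attr(traj, "name") <- "trajectory"
  write_wireframe_obj(c(list(traj), frame_wireframe(spec)), geometry_path)
  invisible(c(report = report_path, geometry = geometry_path))
}

#' Read a plan report written by [export_plan()]
#'
#' @param path JSON report path.
#' @return A `trajectory_plan` (report fields only).
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    target_ras = unlist(x$target_ras),
    entry_ras = unlist(x$entry_ras),
    target_leksell = unlist(x$target_leksell),
    arc_deg = x$arc_deg,
    ring_deg = x$ring_deg,
    trajectory_length_mm = x$trajectory_length_mm,
    rmse_mm = x$rmse_mm,
    registration_warning = x$registration_warning),
    class = "trajectory_plan")
}
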