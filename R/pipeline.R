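# Orchestration: load volume -> detect fiducials -> register -> plan ->
# export, plus batch validation against a second plan set or ground truth.
# Every run writes a manifest echoing the configuration so outputs can be
# reproduced exactly.

.frame_from_config <- function(config) {
  frame_spec(
    plate_separation = config$frame_sep %||% 190,
    fiducial_width = config$frame_width %||% 120,
    fiducial_height = config$frame_height %||% 120,
    center = config$frame_center %||% c(100, 100, 100),
    rmse_warning = config$rmse_warn %||% 1.0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(package = "stereoframe",
                     version = as.character(utils::packageVersion("stereoframe")),
                     config = config), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", path, call. = FALSE)
}

#' Run the full planning pipeline
#'
#' Loads the volume, detects the four localizer vertices from the seeds,
#' registers the frame, plans the target-entry trajectory and writes the
#' plan report, geometry, registration result and a manifest to the output
#' directory. The registration RMSE is logged to stderr, with a warning when
#' it exceeds the configured threshold.
#'
#' @param config Named list (or [read_run_config()] result) with entries
#'   `volume` (NIfTI path or DICOM directory), `seeds` (CSV/JSON seed file),
#'   `target` and `entry` (RAS mm, numeric length 3), `out` (output
#'   directory), and optionally `frame_sep`, `frame_width`, `frame_height`,
#'   `frame_center`, `rmse_warn`, `lmit_radius`, `lmit_threshold`.
#' @return The `trajectory_plan`, invisibly.
#' @export
run_plan <- function(config) {
  for (need in c("volume", "seeds", "target", "entry", "out"))
    if (is.null(config[[need]]))
      stop("run_plan: config entry '", need, "' is required", call. = FALSE)
  if (!file.exists(config$volume) && !dir.exists(config$volume))
    stop("run_plan: volume not found: ", config$volume, call. = FALSE)
  if (!file.exists(config$seeds))
    stop("run_plan: seeds file not found: ", config$seeds, call. = FALSE)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- .frame_from_config(config)
  radius <- config$lmit_radius %||% 10
  threshold <- config$lmit_threshold %||% 500

  v <- load_volume(config$volume)
  seeds <- read_seeds(config$seeds)
  fids <- detect_fiducials(v, seeds, radius = radius, threshold = threshold)
  reg <- register_frame(fids, spec)
  message(sprintf("frame registration RMSE: %.3f mm", reg$rmse_mm))
  if (reg$warning)
    warning(sprintf("registration RMSE %.3f mm exceeds %.2f mm; re-seeding recommended",
                    reg$rmse_mm, spec$rmse_warning), call. = FALSE)
  plan <- plan_trajectory(as.numeric(config$target),
                          as.numeric(config$entry), reg, spec,
                          arc_offset_deg = config$arc_offset %||% 0,
                          ring_offset_deg = config$ring_offset %||% 0)
  write_fiducials(fids, file.path(out_dir, "fiducials.csv"))
  write_registration_json(reg, file.path(out_dir, "registration.json"))
  write_transform(reg$transform, file.path(out_dir, "transform.txt"))
  export_plan(plan, spec,
              report_path = file.path(out_dir, "plan.json"),
              geometry_path = file.path(out_dir, "plan_geometry.obj"))
  con <- file(file.path(out_dir, "plan.txt"), "w")
  sink(con); print(plan); sink()
  close(con)
  .write_manifest(config, out_dir)
  invisible(plan)
}

#' Run agreement validation between two plan sets
#'
#' Reads two plan tables (CSV or JSON with columns `case`, `x`, `y`, `z` and
#' optionally `arc`, `ring`), computes the agreement report and writes it as
#' JSON and text.
#'
#' @param config Named list with `plans_a`, `plans_b` (file paths) and `out`
#'   (output directory).
#' @return The `agreement_report`, invisibly.
#' @export
run_validation <- function(config) {
  for (need in c("plans_a", "plans_b", "out"))
    if (is.null(config[[need]]))
      stop("run_validation: config entry '", need, "' is required",
           call. = FALSE)
  read_plans <- function(path) {
    if (!file.exists(path))
      stop("run_validation: plan file not found: ", path, call. = FALSE)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    } else utils::read.csv(path)
  }
  a <- read_plans(config$plans_a)
  b <- read_plans(config$plans_b)
  report <- agreement_report(a, b)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_agreement_json(report, file.path(out_dir, "agreement.json"),
                       text_path = file.path(out_dir, "agreement.txt"))
  .write_manifest(config, out_dir)
  invisible(report)
}

#' Generate a phantom and write it to disk
#'
#' Convenience wrapper used by the command-line interface: generates a
#' phantom, optionally embeds a target marker, and writes the NIfTI volume,
#' the ground-truth JSON and a seeds file (exact rod positions at mid-height,
#' offset 0) to the output directory.
#'
#' @param config Named list with `out` and optionally `dims`, `spacing`,
#'   `pose_rot` (degrees, length 3), `pose_trans` (mm, length 3),
#'   `noise_sigma`, `marker` (RAS mm, length 3), `seed`, plus the frame
#'   entries understood by [run_plan()].
#' @return List with `volume_path`, `truth_path`, `seeds_path`, invisibly.
#' @export
run_phantom <- function(config) {
  if (is.null(config$out))
    stop("run_phantom: config entry 'out' is required", call. = FALSE)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rot <- config$pose_rot %||% c(0, 0, 0)
  pose <- rigid_transform(rotation_euler(rot[1], rot[2], rot[3]),
                          config$pose_trans %||% c(0, 0, 0), tol = 1e-6)
  cfg <- phantom_config(dims = config$dims %||% c(256, 256, 200),
                        spacing = config$spacing %||% 1,
                        frame = .frame_from_config(config),
                        pose = pose,
                        noise_sigma = config$noise_sigma %||% 0,
                        rng_seed = config$seed %||% 1L)
  ph <- generate_phantom(cfg)
  if (!is.null(config$marker)) {
    ph$volume <- embed_target_marker(ph$volume, as.numeric(config$marker))
    ph$truth$marker_center <- as.numeric(config$marker)
  }
  volume_path <- file.path(out_dir, "phantom.nii.gz")
  write_volume(ph$volume, volume_path)
  truth_path <- file.path(out_dir, "truth.json")
  write_truth_json(ph$truth, truth_path)
  seeds <- perturb_seeds(ph$truth, n_sets = 1, max_offset = 0,
                         rng_seed = config$seed %||% 1L)[[1]]
  seeds_path <- file.path(out_dir, "seeds.csv")
  write_seeds(seeds, seeds_path)
  .write_manifest(config, out_dir)
  invisible(list(volume_path = volume_path, truth_path = truth_path,
                 seeds_path = seeds_path))
}
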