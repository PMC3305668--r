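# End-to-end "one-button" pipeline: detect the two hole projections, extract
# landmarks, solve the 6-DOF pose, and emit the guidance overlays, plus the
# simulate sub-command that produces reproducible synthetic cases.

#' Run the full guidance pipeline on one radiograph
#'
#' Executes detect -> landmarks -> solve -> overlay and writes a JSON run
#' report, an overlay JSON and an annotated PNG into `out_dir`. The report
#' echoes the configuration (with a hash) and the seed so any run can be
#' replayed. Deterministic given the image and configuration.
#'
#' @param image_path path to a grayscale PNG/PGM radiograph.
#' @param config_path path to a YAML/JSON configuration (see
#'   [default_config()]); `NULL` uses the defaults.
#' @param out_dir output directory (created if needed).
#' @return A `run_report` list (invisibly written to `report.json`):
#'   `converged`, `pose` (quaternion + translation), `rms_residual_px`,
#'   `branch`, `overlays`, `warnings`, `timings_s`, `config_hash`.
#' @export
run_pipeline <- function(image_path, config_path = NULL, out_dir = ".") {
  t_all <- proc.time()[3]
  config <- if (is.null(config_path)) default_config() else read_config(config_path)
  obj <- config_objects(config)
  camera <- obj$camera; nail <- obj$nail; jig <- obj$jig
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  warnings_seen <- character(0)
  img <- read_image(image_path)
  t_read <- proc.time()[3]

  det <- withCallingHandlers(
    detect_lens_regions(img, camera,
                        min_area_px = config$detection$min_area_px,
                        min_solidity = config$detection$min_solidity,
                        smooth_sigma = config$detection$smooth_sigma),
    nailguide_occluded_hole = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  t_detect <- proc.time()[3]

  rim_ratio <- rim_offset_mm(nail) / nail$hole_radius_mm
  landmarks <- lapply(det, extract_landmarks,
                      circular_contrast = config$detection$circular_contrast,
                      rim_ratio = rim_ratio)
  t_landmarks <- proc.time()[3]

  lm_both <- if (length(landmarks) >= 2) landmarks[1:2] else
    list(landmarks[[1]], NULL)
  sol <- tryCatch(
    solve_pose(lm_both, camera, nail),
    nailguide_under_constrained = function(e) {
      warnings_seen <<- c(warnings_seen, conditionMessage(e))
      pose_solution(NULL, Inf, numeric(0), "under-constrained", FALSE, 0L)
    }
  )
  t_solve <- proc.time()[3]

  overlays <- list()
  if (isTRUE(sol$converged)) {
    for (k in 1:2) {
      overlays[[k]] <- compute_overlay(
        sol$pose, camera, nail, jig, k,
        skin_offset_mm = config$guidance$skin_offset_mm)
    }
    render_overlay(img, overlays, file.path(out_dir, "overlay.png"))
    jsonlite::write_json(
      lapply(overlays, overlay_to_list),
      file.path(out_dir, "overlay.json"), auto_unbox = TRUE, digits = NA)
  }
  t_overlay <- proc.time()[3]

  report <- list(
    input = list(image = image_path,
                 config = if (is.null(config_path)) "defaults" else config_path),
    converged = isTRUE(sol$converged),
    pose = if (!is.null(sol$pose)) pose_to_list(sol$pose) else NULL,
    rms_residual_px = sol$rms_residual_px,
    branch = sol$branch_id,
    iterations = sol$iterations,
    n_holes_detected = length(det),
    overlays = lapply(overlays, overlay_to_list),
    warnings = warnings_seen,
    seed = config$seed,
    config_hash = config_hash(config),
    config = config,
    timings_s = list(read = t_read - t_all, detect = t_detect - t_read,
                     landmarks = t_landmarks - t_detect,
                     solve = t_solve - t_landmarks,
                     overlay = t_overlay - t_solve)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s, %d hole(s), rms %.3g px, branch %s\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_holes_detected, x$rms_residual_px, x$branch))
  invisible(x)
}

overlay_to_list <- function(ov) {
  conic_list <- function(cc) {
    if (is.null(cc) || is.null(cc$center_px)) return(NULL)
    list(center_px = cc$center_px, semi_axes_px = cc$semi_axes_px,
         orientation_rad = cc$orientation_rad, coef = cc$coef)
  }
  list(hole_id = ov$hole_index,
       small_target = conic_list(ov$small_target),
       large_target = conic_list(ov$large_target),
       incision_px = ov$incision_point_px,
       entry_px = ov$entry_point_px,
       axis_line = ov$axis_line)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Generate a synthetic fixture case on disk
#'
#' Writes the radiograph (16-bit PGM), a ground-truth JSON sidecar (pose,
#' per-hole contours, seed) and the matching configuration file into
#' `out_dir`.
#'
#' @param scenario scenario id accepted by [make_fixture()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param camera,nail optional scene overrides.
#' @return list of written file paths.
#' @export
cmd_simulate <- function(scenario, seed = 1L, out_dir = ".",
                         camera = NULL, nail = NULL) {
  fx <- make_fixture(scenario, seed = seed, camera = camera, nail = nail)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  img_path <- file.path(out_dir, sprintf("%s_seed%d.pgm", scenario, seed))
  write_image(fx$image$pixels, img_path, bit_depth = 16L)
  paths <- img_path

  contours <- lapply(fx$image$ground_truth_contours, function(lc) {
    if (is.null(lc)) return(NULL)
    list(is_circular = lc$is_circular,
         points = lc$points,
         tips = lc$tips)
  })
  sidecar <- list(
    scenario = scenario, seed = seed,
    pose = pose_to_list(fx$image$ground_truth),
    obliquity_deg = hole_obliquity_deg(fx$nail, fx$image$ground_truth, 1),
    contours = contours,
    shift_px = fx$shift_px
  )
  gt_path <- file.path(out_dir, sprintf("%s_seed%d_truth.json", scenario, seed))
  jsonlite::write_json(sidecar, gt_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, gt_path)

  if (!is.null(fx$image_b)) {
    b_path <- file.path(out_dir, sprintf("%s_seed%d_frame2.pgm", scenario, seed))
    write_image(fx$image_b$pixels, b_path, bit_depth = 16L)
    paths <- c(paths, b_path)
  }

  config <- default_config()
  config$camera <- camera_to_list(fx$camera)
  config$nail <- nail_to_list(fx$nail)
  config$seed <- seed
  cfg_path <- file.path(out_dir, sprintf("%s_seed%d_config.yaml", scenario, seed))
  write_config(config, cfg_path)
  c(paths, cfg_path)
}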