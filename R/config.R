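# Run configuration: one YAML/JSON document holding the camera, nail, jig
# and algorithm parameter blocks. Everything is validated before any
# computation runs.

#' Default run configuration
#'
#' @return nested list with blocks `camera`, `nail`, `jig`, `detection`,
#'   `solver`, `guidance`, plus `seed` and `verbosity`.
#' @export
default_config <- function() {
  list(
    camera = camera_to_list(fixture_camera()),
    nail = nail_to_list(fixture_nail("parallel")),
    jig = jig_to_list(jig_spec()),
    detection = list(min_area_px = 30, min_solidity = 0.85, smooth_sigma = 1,
                     circular_contrast = 3),
    solver = list(max_iter = 200),
    guidance = list(skin_offset_mm = 30, drill_diameter_mm = 3.2),
    seed = 1L,
    verbosity = 1L
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Missing optional blocks are filled from [default_config()]; missing or
#' invalid required blocks raise an error naming the offending field.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    stop("unsupported config format '", ext, "' (use yaml or json)")
  }
  validate_config(raw)
}

#' Write a configuration to YAML or JSON
#' @param config configuration list.
#' @param path destination path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(config, path)
  } else if (ext == "json") {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config format '", ext, "'")
  }
  invisible(path)
}

#' Validate a configuration list
#'
#' Required blocks (`camera`, `nail`) must be present and must construct
#' valid objects; optional blocks are defaulted. Error messages name the
#' failing block.
#'
#' @param config raw configuration list.
#' @return validated configuration list with all blocks present.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list/mapping")
  def <- default_config()
  for (block in c("camera", "nail")) {
    if (is.null(config[[block]])) {
      stop(sprintf("config error: required block '%s' is missing", block))
    }
  }
  out <- utils::modifyList(def, config)
  tryCatch(camera_from_list(out$camera),
           error = function(e) stop("config error in 'camera': ",
                                    conditionMessage(e), call. = FALSE))
  tryCatch(nail_from_list(out$nail),
           error = function(e) stop("config error in 'nail': ",
                                    conditionMessage(e), call. = FALSE))
  tryCatch(jig_from_list(out$jig),
           error = function(e) stop("config error in 'jig': ",
                                    conditionMessage(e), call. = FALSE))
  if (!is.numeric(out$seed)) stop("config error: 'seed' must be numeric")
  out
}

config_objects <- function(config) {
  list(camera = camera_from_list(config$camera),
       nail = nail_from_list(config$nail),
       jig = jig_from_list(config$jig))
}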