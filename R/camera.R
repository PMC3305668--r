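# Cone-beam camera model of the C-arm image intensifier.

#' Cone-beam camera model
#'
#' Ideal point-source perspective camera: the X-ray source sits at the origin
#' of a right-handed frame with +z toward the detector plane at distance
#' `sdd_mm` (source-to-detector distance). Detector pixels are square with
#' pitch `pixel_pitch_mm`; pixel coordinates are 0-based with `u` to the right
#' and `v` down, origin at the top-left corner.
#'
#' Defaults describe a typical mobile image intensifier producing 1024 x 1024
#' gray-value images. No lens/pincushion distortion is modeled.
#'
#' @param sdd_mm source-to-detector distance in mm (> 0).
#' @param pixel_pitch_mm detector sampling pitch in mm per pixel (> 0).
#' @param principal_point_px length-2 pixel coordinate where the central ray
#'   meets the detector; must lie inside the image bounds.
#' @param image_size_px length-2 integer `(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' project_point(cam, c(0, 0, 500))
#' @export
camera_model <- function(sdd_mm = 1000, pixel_pitch_mm = 0.3,
                         principal_point_px = c(512, 512),
                         image_size_px = c(1024, 1024)) {
  stopifnot(length(principal_point_px) == 2L, length(image_size_px) == 2L)
  if (!is.finite(sdd_mm) || sdd_mm <= 0) stop("sdd_mm must be positive")
  if (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop("pixel_pitch_mm must be positive")
  }
  pp <- as.numeric(principal_point_px)
  sz <- as.numeric(image_size_px)
  if (any(pp < 0) || pp[1] > sz[1] - 1 || pp[2] > sz[2] - 1) {
    stop("principal point must lie inside the image bounds")
  }
  structure(
    list(sdd_mm = sdd_mm, pixel_pitch_mm = pixel_pitch_mm,
         principal_point_px = pp, image_size_px = as.integer(sz)),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> SDD %.1f mm, pitch %.3f mm/px, pp (%.1f, %.1f), image %dx%d\n",
    x$sdd_mm, x$pixel_pitch_mm, x$principal_point_px[1], x$principal_point_px[2],
    x$image_size_px[1], x$image_size_px[2]
  ))
  invisible(x)
}

#' Project 3D camera-frame points to detector pixels
#'
#' Pure perspective: `u = pu + (x/z) * SDD / pitch` and likewise for `v`.
#' Points must have positive depth (z > 0, i.e. on the detector side of the
#' source).
#'
#' @param camera a [camera_model()].
#' @param p length-3 point or n x 3 matrix of camera-frame points in mm.
#' @return length-2 pixel coordinate, or n x 2 matrix for matrix input.
#' @export
project_point <- function(camera, p) {
  one <- !is.matrix(p)
  if (one) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) == 3L)
  if (any(p[, 3] <= 0)) {
    stop("degenerate projection: point has non-positive depth (z <= 0)")
  }
  m <- camera$sdd_mm / (p[, 3] * camera$pixel_pitch_mm)
  uv <- cbind(camera$principal_point_px[1] + p[, 1] * m,
              camera$principal_point_px[2] + p[, 2] * m)
  colnames(uv) <- c("u", "v")
  if (one) uv[1, ] else uv
}

# Map pixel coordinates to detector-plane ray directions (n x 3, z = SDD).
pixel_to_ray <- function(camera, uv) {
  if (!is.matrix(uv)) uv <- matrix(uv, nrow = 1)
  cbind((uv[, 1] - camera$principal_point_px[1]) * camera$pixel_pitch_mm,
        (uv[, 2] - camera$principal_point_px[2]) * camera$pixel_pitch_mm,
        camera$sdd_mm)
}

# Homography taking homogeneous pixel coords (u, v, 1) to ray directions.
camera_pixel_to_dir_matrix <- function(camera) {
  ptc <- camera$pixel_pitch_mm
  pp <- camera$principal_point_px
  matrix(c(ptc, 0, -ptc * pp[1],
           0, ptc, -ptc * pp[2],
           0, 0, camera$sdd_mm), 3, 3, byrow = TRUE)
}

camera_to_list <- function(camera) {
  list(sdd_mm = camera$sdd_mm, pixel_pitch_mm = camera$pixel_pitch_mm,
       principal_point_px = camera$principal_point_px,
       image_size_px = camera$image_size_px)
}

camera_from_list <- function(x) {
  camera_model(sdd_mm = x$sdd_mm, pixel_pitch_mm = x$pixel_pitch_mm,
               principal_point_px = unlist(x$principal_point_px),
               image_size_px = unlist(x$image_size_px))
}
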