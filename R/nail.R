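# Parametric model of the distal nail segment and its two interlocking holes.
#
# Nail frame: the nail axis is +z, hole centers lie on the axis at their
# axial stations, hole axes are unit vectors perpendicular to the nail axis
# (mediolateral ML = +x, anteroposterior AP = +y by convention).

#' Specification of one interlocking hole
#'
#' @param axial_station_mm position of the hole center along the nail axis.
#' @param axis_dir_nail_frame length-3 unit vector of the hole axis in the
#'   nail frame; must be perpendicular to the nail axis (z).
#' @param label `"ML"` or `"AP"`.
#' @return An object of class `hole_spec`.
#' @export
hole_spec <- function(axial_station_mm, axis_dir_nail_frame, label = "ML") {
  a <- as.numeric(axis_dir_nail_frame)
  stopifnot(length(a) == 3L)
  n <- sqrt(sum(a^2))
  if (n < 1e-12) stop("hole axis must be a nonzero vector")
  a <- a / n
  if (abs(a[3]) > 1e-9) stop("hole axis must be perpendicular to the nail axis")
  if (!label %in% c("ML", "AP")) stop("label must be 'ML' or 'AP'")
  structure(list(axial_station_mm = axial_station_mm,
                 axis_dir_nail_frame = a, label = label),
            class = "hole_spec")
}

#' Specification of the distal nail segment
#'
#' Defaults follow a 10 mm titanium tibial nail with a 2 mm hole radius
#' (clearance over the 3.9 mm locking bolts drilled at 3.2 mm) and two holes
#' 12 mm apart. Both orthogonal (one ML + one AP) and parallel hole layouts
#' are supported.
#'
#' @param outer_radius_mm nail outer radius R in mm.
#' @param hole_radius_mm interlocking-hole radius r_h in mm (`2 r_h < 2 R`).
#' @param holes list of exactly two [hole_spec()] with distinct stations.
#' @param length_mm modeled length of the distal segment, centered on the
#'   mid-point of the two hole stations.
#' @return An object of class `nail_spec`.
#' @export
nail_spec <- function(outer_radius_mm = 5, hole_radius_mm = 2,
                      holes = list(
                        hole_spec(0, c(1, 0, 0), "ML"),
                        hole_spec(12, c(0, 1, 0), "AP")
                      ),
                      length_mm = 80) {
  stopifnot(outer_radius_mm > 0, hole_radius_mm > 0, length_mm > 0)
  if (hole_radius_mm >= outer_radius_mm) {
    stop("hole diameter must be smaller than the nail diameter")
  }
  if (length(holes) != 2L || !all(vapply(holes, inherits, TRUE, "hole_spec"))) {
    stop("exactly two hole_spec objects are required")
  }
  s <- vapply(holes, function(h) h$axial_station_mm, numeric(1))
  if (abs(s[1] - s[2]) < 1e-9) stop("hole axial stations must be distinct")
  structure(list(outer_radius_mm = outer_radius_mm,
                 hole_radius_mm = hole_radius_mm,
                 holes = holes, length_mm = length_mm),
            class = "nail_spec")
}

#' @export
print.nail_spec <- function(x, ...) {
  cat(sprintf(
    "<nail_spec> R = %.1f mm, r_h = %.1f mm, holes %s@%.1f / %s@%.1f mm\n",
    x$outer_radius_mm, x$hole_radius_mm,
    x$holes[[1]]$label, x$holes[[1]]$axial_station_mm,
    x$holes[[2]]$label, x$holes[[2]]$axial_station_mm
  ))
  invisible(x)
}

# Default rim offset: the rim planes sit at +/- sqrt(R^2 - r_h^2) from the
# nail axis (plane of inner tangency between hole and outer cylinder).
rim_offset_mm <- function(nail) {
  sqrt(nail$outer_radius_mm^2 - nail$hole_radius_mm^2)
}

#' Rim circles of an interlocking hole in camera frame
#'
#' The two openings of a hole on the nail surface are modeled as planar
#' circles of the hole radius, perpendicular to the hole axis, at signed
#' offsets of `sqrt(R^2 - r_h^2)` from the nail axis (planar-rim
#' approximation; the exact rim curve of two intersecting cylinders is
#' slightly non-planar, and the ray-cast renderer serves as the exact oracle
#' bounding that bias).
#'
#' @param nail a [nail_spec()].
#' @param pose a [nail_pose()] mapping nail frame to camera frame.
#' @param hole_index 1 or 2.
#' @return list of two [circle3d()] in camera frame (offsets +/- along the
#'   hole axis).
#' @export
hole_rim_circles <- function(nail, pose, hole_index) {
  stopifnot(hole_index %in% c(1L, 2L))
  h <- nail$holes[[hole_index]]
  off <- rim_offset_mm(nail)
  ctr_n <- c(0, 0, h$axial_station_mm)
  a_n <- h$axis_dir_nail_frame
  ctr_c <- pose_apply(pose, ctr_n)
  a_c <- as.numeric(pose$rotation %*% a_n)
  list(
    circle3d(ctr_c + off * a_c, a_c, nail$hole_radius_mm),
    circle3d(ctr_c - off * a_c, a_c, nail$hole_radius_mm)
  )
}

# Hole center and axis direction in camera frame.
hole_axis_camera <- function(nail, pose, hole_index) {
  h <- nail$holes[[hole_index]]
  list(center = pose_apply(pose, c(0, 0, h$axial_station_mm)),
       axis = as.numeric(pose$rotation %*% h$axis_dir_nail_frame))
}

# Angle (deg) between the hole axis and the ray from source to hole center.
hole_obliquity_deg <- function(nail, pose, hole_index) {
  hc <- hole_axis_camera(nail, pose, hole_index)
  line_angle_deg(hc$axis, hc$center)
}

nail_to_list <- function(nail) {
  list(
    outer_radius_mm = nail$outer_radius_mm,
    hole_radius_mm = nail$hole_radius_mm,
    length_mm = nail$length_mm,
    holes = lapply(nail$holes, function(h) {
      list(axial_station_mm = h$axial_station_mm,
           axis_dir_nail_frame = h$axis_dir_nail_frame, label = h$label)
    })
  )
}

nail_from_list <- function(x) {
  nail_spec(
    outer_radius_mm = x$outer_radius_mm, hole_radius_mm = x$hole_radius_mm,
    length_mm = x$length_mm,
    holes = lapply(x$holes, function(h) {
      hole_spec(h$axial_station_mm, unlist(h$axis_dir_nail_frame), h$label)
    })
  )
}

pose_to_list <- function(pose) {
  list(quaternion = rotation_to_quaternion(pose$rotation),
       translation_mm = pose$translation_mm)
}

pose_from_list <- function(x) {
  nail_pose(quaternion_to_rotation(unlist(x$quaternion)),
            unlist(x$translation_mm))
}
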