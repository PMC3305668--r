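# Surgeon-facing guidance: targeting ellipses for the two-ring drill jig,
# the skin-incision landmark, and closed-loop alignment verification.
#
# The jig is a drill sleeve with two concentric radio-opaque rings (one
# small, near the bone; one large, further up the sleeve). When each ring's
# projection coincides with its computed target ellipse, the sleeve axis is
# coaxial with the interlocking hole: the small ring pins the entry point,
# the large ring (far from the bone) pins the direction.

#' Targeting jig specification
#'
#' Default dimensions place the small ring at the bone-contact tip and the
#' large ring 80 mm up the sleeve: with the default camera geometry a 1 px
#' ring-match error then maps to well under 1 degree of axis error.
#'
#' @param small_ring_radius_mm radius of the distal (bone-side) ring.
#' @param large_ring_radius_mm radius of the proximal ring (> small).
#' @param small_ring_offset_mm,large_ring_offset_mm positions of the ring
#'   planes along the sleeve axis measured from the bone-contact tip
#'   (large > small >= 0).
#' @param sleeve_inner_diameter_mm bore of the drill sleeve (fits the 3.2 mm
#'   drill bit used for 3.9 mm locking bolts).
#' @return An object of class `jig_spec`.
#' @export
jig_spec <- function(small_ring_radius_mm = 8, large_ring_radius_mm = 25,
                     small_ring_offset_mm = 0, large_ring_offset_mm = 80,
                     sleeve_inner_diameter_mm = 3.3) {
  if (large_ring_radius_mm <= small_ring_radius_mm) {
    stop("large ring must be larger than the small ring")
  }
  if (small_ring_offset_mm < 0 || large_ring_offset_mm <= small_ring_offset_mm) {
    stop("ring offsets must satisfy large > small >= 0")
  }
  structure(
    list(small_ring_radius_mm = small_ring_radius_mm,
         large_ring_radius_mm = large_ring_radius_mm,
         small_ring_offset_mm = small_ring_offset_mm,
         large_ring_offset_mm = large_ring_offset_mm,
         sleeve_inner_diameter_mm = sleeve_inner_diameter_mm),
    class = "jig_spec"
  )
}

jig_to_list <- function(jig) unclass(jig)
jig_from_list <- function(x) do.call(jig_spec, x)

#' Compute the targeting overlay for one hole
#'
#' The drilling direction is the hole-axis sign pointing toward the X-ray
#' source (the surgeon works on the source side). Two circles with the jig's
#' ring radii are placed on the hole axis, perpendicular to it, at the bone
#' entry point plus each ring's offset; their exact conic projections are the
#' small and large target ellipses. The incision landmark is the projection
#' of the axis point `skin_offset_mm` above the bone entry.
#'
#' @param pose a [nail_pose()] (typically from a converged solve).
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param jig a [jig_spec()].
#' @param hole_index 1 or 2.
#' @param skin_offset_mm distance from bone entry to the skin along the
#'   drilling direction.
#' @return An object of class `target_overlay`: `small_target` and
#'   `large_target` ([conic2d()]), `incision_point_px`, `axis_line`
#'   (homogeneous line), `entry_point_px` and the 3D construction in
#'   `geometry`.
#' @export
compute_overlay <- function(pose, camera, nail, jig = jig_spec(), hole_index,
                            skin_offset_mm = 30) {
  hc <- hole_axis_camera(nail, pose, hole_index)
  toward_source <- -sum(hc$axis * hc$center)
  if (abs(toward_source) < 1e-9) {
    stop("side selection failed: hole axis is perpendicular to the view ray")
  }
  e_dir <- hc$axis * sign(toward_source)   # drilling direction, toward source
  entry <- hc$center + nail$outer_radius_mm * e_dir
  small_c <- circle3d(entry + jig$small_ring_offset_mm * e_dir, e_dir,
                      jig$small_ring_radius_mm)
  large_c <- circle3d(entry + jig$large_ring_offset_mm * e_dir, e_dir,
                      jig$large_ring_radius_mm)
  small_t <- project_circle(camera, small_c)
  large_t <- project_circle(camera, large_c)
  incision <- project_point(camera, entry + skin_offset_mm * e_dir)
  p_a <- project_point(camera, entry)
  p_b <- project_point(camera, entry + 50 * e_dir)
  l <- c(p_a[2] - p_b[2], p_b[1] - p_a[1],
         p_a[1] * p_b[2] - p_b[1] * p_a[2])
  l <- l / sqrt(sum(l[1:2]^2))
  structure(
    list(hole_index = hole_index,
         small_target = small_t, large_target = large_t,
         incision_point_px = incision, axis_line = l,
         entry_point_px = p_a,
         geometry = list(entry_mm = entry, drill_dir = e_dir,
                         small_circle = small_c, large_circle = large_c)),
    class = "target_overlay"
  )
}

#' @export
print.target_overlay <- function(x, ...) {
  cat(sprintf(
    "<target_overlay> hole %d: incision (%.1f, %.1f) px, small target at (%.1f, %.1f) px\n",
    x$hole_index, x$incision_point_px[1], x$incision_point_px[2],
    x$small_target$center_px[1], x$small_target$center_px[2]
  ))
  invisible(x)
}

#' Alignment error of a jig placement against a hole
#'
#' Reports the angle between the sleeve axis and the hole axis, the lateral
#' offset of the sleeve axis at the bone entry point, and whether a drill of
#' the given diameter travelling along the sleeve axis clears the hole
#' cylinder over the full channel (so the screw can pass).
#'
#' @param jig_tip_mm 3D bone-contact point of the sleeve axis (camera frame).
#' @param jig_axis unit direction of the sleeve axis (camera frame).
#' @param pose solved [nail_pose()].
#' @param nail a [nail_spec()].
#' @param hole_index 1 or 2.
#' @param drill_diameter_mm drill bit diameter (default 3.2 mm).
#' @return An object of class `alignment_report` with `angular_deviation_deg`,
#'   `lateral_offset_mm` and `would_screw_pass`.
#' @export
alignment_error <- function(jig_tip_mm, jig_axis, pose, nail, hole_index,
                            drill_diameter_mm = 3.2) {
  hc <- hole_axis_camera(nail, pose, hole_index)
  a_hat <- unit3(hc$axis)
  j_hat <- unit3(jig_axis)
  ang <- line_angle_deg(a_hat, j_hat)
  entry <- hc$center + nail$outer_radius_mm * a_hat *
    sign(-sum(a_hat * hc$center))
  d <- entry - jig_tip_mm
  lat <- sqrt(max(sum(d^2) - sum(d * j_hat)^2, 0))
  # drill clearance along the channel: sample sleeve-axis points inside the
  # nail slab (|projection on hole axis from hole center| <= R) and check the
  # radial distance to the hole axis plus the drill radius against r_h
  ja <- sum(j_hat * a_hat)
  pass <- TRUE
  if (abs(ja) < 1e-6) {
    pass <- FALSE                     # sleeve nearly perpendicular to hole
  } else {
    t0 <- sum((jig_tip_mm - hc$center) * a_hat)
    s_lim <- sort(c((nail$outer_radius_mm - t0) / ja,
                    (-nail$outer_radius_mm - t0) / ja))
    for (s in seq(s_lim[1], s_lim[2], length.out = 41)) {
      p <- jig_tip_mm + s * j_hat
      t_ax <- sum((p - hc$center) * a_hat)
      radial <- sqrt(max(sum((p - hc$center)^2) - t_ax^2, 0))
      if (radial + drill_diameter_mm / 2 > nail$hole_radius_mm + 1e-9) {
        pass <- FALSE
        break
      }
    }
  }
  structure(
    list(angular_deviation_deg = ang, lateral_offset_mm = lat,
         would_screw_pass = pass),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(
    "<alignment_report> %.3f deg, %.3f mm lateral, screw %s\n",
    x$angular_deviation_deg, x$lateral_offset_mm,
    if (x$would_screw_pass) "PASSES" else "BLOCKED"
  ))
  invisible(x)
}

# Projections of a jig placement's two rings (for closed-loop testing).
project_jig_rings <- function(camera, jig, jig_tip_mm, jig_axis) {
  a <- unit3(jig_axis)
  list(
    small = project_circle(camera, circle3d(
      jig_tip_mm + jig$small_ring_offset_mm * a, a, jig$small_ring_radius_mm)),
    large = project_circle(camera, circle3d(
      jig_tip_mm + jig$large_ring_offset_mm * a, a, jig$large_ring_radius_mm))
  )
}

#' Render the guidance overlay onto an image file
#'
#' Draws the two target ellipses, the projected drill-axis line, and a cross
#' at the incision landmark over the radiograph, and writes a deterministic
#' RGB PNG. Overlay elements outside the frame are clipped silently.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param overlays a [compute_overlay()] result or list of them.
#' @param out_path output PNG path.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(image, overlays, out_path) {
  stopifnot(is.matrix(image))
  if (inherits(overlays, "target_overlay")) overlays <- list(overlays)
  h <- nrow(image); w <- ncol(image)
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), dim = c(h, w, 3))
  put <- function(uv, channel_rgb) {
    uv <- round(uv)
    ok <- uv[, 1] >= 0 & uv[, 1] <= w - 1 & uv[, 2] >= 0 & uv[, 2] <= h - 1
    uv <- uv[ok, , drop = FALSE]
    if (!nrow(uv)) return(invisible())
    for (ch in 1:3) {
      rgb[cbind(uv[, 2] + 1, uv[, 1] + 1, ch)] <<- channel_rgb[ch]
    }
  }
  tt <- seq(0, 2 * pi, length.out = 720)
  for (ov in overlays) {
    if (!is.null(ov$small_target$center_px)) {
      put(ellipse_points(ov$small_target, tt), c(1, 0.2, 0.2))
    }
    if (!is.null(ov$large_target$center_px)) {
      put(ellipse_points(ov$large_target, tt), c(1, 0.6, 0.1))
    }
    # axis line across the frame
    l <- ov$axis_line
    if (abs(l[2]) > abs(l[1])) {
      us <- seq(0, w - 1, by = 0.5)
      vs <- -(l[1] * us + l[3]) / l[2]
    } else {
      vs <- seq(0, h - 1, by = 0.5)
      us <- -(l[2] * vs + l[3]) / l[1]
    }
    put(cbind(us, vs), c(0.2, 0.8, 1))
    ic <- ov$incision_point_px
    put(cbind(ic[1] + c(-5:5, rep(0, 11)), ic[2] + c(rep(0, 11), -5:5)),
        c(0.2, 1, 0.2))
  }
  png::writePNG(rgb, out_path)
  invisible(out_path)
}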