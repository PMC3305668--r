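# Analytic forward model of the lens-shaped hole projection.
#
# Viewed obliquely, a hole's two rim circles project to two ellipses; rays
# that pass through the hole channel are those inside both, so the bright
# "lens" is the overlap region. Its boundary is two elliptical arcs meeting
# at two tips (the conic intersections). When the beam is aligned with the
# hole axis the two images nest and the projection "appears round".

#' Lens contour container
#'
#' @param points n x 2 matrix of ordered closed contour points (pixels,
#'   subpixel precision; first point not repeated).
#' @param is_circular logical; `TRUE` for the aligned, round-appearing case.
#' @param tips 2 x 2 matrix of tip points, or `NULL` when circular.
#' @param tip_idx indices of the tips within `points`, or `NULL`.
#' @param arcs list of two index vectors partitioning the contour tip-to-tip,
#'   or `NULL` when circular.
#' @param arc_conics list of two [conic2d()] (one per arc), when known.
#' @param circle_fit list(center_px, radius_px) when `is_circular`.
#' @return An object of class `lens_contour`.
#' @export
lens_contour_object <- function(points, is_circular = FALSE, tips = NULL,
                                tip_idx = NULL, arcs = NULL, arc_conics = NULL,
                                circle_fit = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  structure(
    list(points = points, is_circular = is_circular, tips = tips,
         tip_idx = tip_idx, arcs = arcs, arc_conics = arc_conics,
         circle_fit = circle_fit),
    class = "lens_contour"
  )
}

#' @export
print.lens_contour <- function(x, ...) {
  if (x$is_circular) {
    cat(sprintf("<lens_contour> circular, %d points, r = %.2f px\n",
                nrow(x$points), x$circle_fit$radius_px))
  } else {
    cat(sprintf("<lens_contour> lens, %d points, 2 tips\n", nrow(x$points)))
  }
  invisible(x)
}

empty_lens_error <- function(hole_index) {
  stop(structure(
    class = c("nailguide_empty_lens", "error", "condition"),
    list(message = sprintf(
      "empty lens: hole %d is too oblique, no ray passes the channel", hole_index),
      call = NULL)
  ))
}

# Sample an elliptical arc between parameters t1 and t2, walking in the
# direction whose midpoint lies inside `other` (conic value < 0).
sample_arc_inside <- function(conic, t1, t2, other, n) {
  dt <- (t2 - t1) %% (2 * pi)
  mid_fwd <- ellipse_points(conic, t1 + dt / 2)
  fwd_in <- conic_eval(other, mid_fwd) < 0
  if (fwd_in) {
    tt <- t1 + seq(0, dt, length.out = n)
  } else {
    tt <- t1 - seq(0, 2 * pi - dt, length.out = n)
  }
  list(points = ellipse_points(conic, tt), t = tt)
}

#' Analytic lens contour of a hole projection
#'
#' Projects both rim circles of the hole and intersects their conic images.
#' Generic oblique views give a two-arc lens with two tips; near-aligned views
#' (one rim image nested inside the other, or coincident images) give a
#' circular contour with `is_circular = TRUE`; extreme obliquity where the
#' images separate raises an empty-lens error (no ray passes the channel).
#'
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param pose a [nail_pose()].
#' @param hole_index 1 or 2.
#' @param n_points approximate number of contour points.
#' @return A [lens_contour_object()].
#' @export
lens_contour <- function(camera, nail, pose, hole_index, n_points = 256,
                         circ_tol_px = 1.0) {
  rims <- hole_rim_circles(nail, pose, hole_index)
  e1 <- project_circle(camera, rims[[1]])
  e2 <- project_circle(camera, rims[[2]])

  # round-appearing degenerate case: the two rim images are indistinguishable
  # at pixel resolution (maximal boundary-to-boundary gap below tolerance)
  if (ellipse_boundary_gap(e1, e2) <= circ_tol_px) {
    return(circular_lens(e1, e2, n_points))
  }

  ix <- intersect_conics(e1, e2)
  if (ix$coincident) return(circular_lens(e1, e2, n_points))
  if (nrow(ix$points) == 0) {
    # nested (still round-appearing) or fully separated (beyond grazing)
    if (all(conic_eval(e2, ellipse_points(e1, seq(0, 2 * pi, length.out = 33))) < 0) ||
        all(conic_eval(e1, ellipse_points(e2, seq(0, 2 * pi, length.out = 33))) < 0)) {
      return(circular_lens(e1, e2, n_points))
    }
    empty_lens_error(hole_index)
  }

  tips <- ix$points
  if (nrow(tips) > 2) {
    # keep the two most separated crossings (over-grazing corner case)
    dmax <- -1; best <- c(1L, 2L)
    for (i in 1:(nrow(tips) - 1)) for (j in (i + 1):nrow(tips)) {
      d <- sum((tips[i, ] - tips[j, ])^2)
      if (d > dmax) { dmax <- d; best <- c(i, j) }
    }
    tips <- tips[best, , drop = FALSE]
  }
  if (nrow(tips) < 2) empty_lens_error(hole_index)

  n_arc <- max(16L, ceiling(n_points / 2))
  t1a <- ellipse_param_of(e1, tips[1, ]); t1b <- ellipse_param_of(e1, tips[2, ])
  t2a <- ellipse_param_of(e2, tips[1, ]); t2b <- ellipse_param_of(e2, tips[2, ])
  arc1 <- sample_arc_inside(e1, t1a, t1b, e2, n_arc)   # tip1 -> tip2 on e1
  arc2 <- sample_arc_inside(e2, t2b, t2a, e1, n_arc)   # tip2 -> tip1 on e2
  pts <- rbind(arc1$points, arc2$points[-c(1, n_arc), , drop = FALSE])
  idx1 <- seq_len(n_arc)
  idx2 <- c(n_arc, n_arc + seq_len(n_arc - 2L), 1L)
  lens_contour_object(
    pts, is_circular = FALSE, tips = tips, tip_idx = c(1L, n_arc),
    arcs = list(idx1, idx2), arc_conics = list(e1, e2)
  )
}

# Maximal boundary-to-boundary distance between two ellipses, first order
# (|conic value| / |gradient|) over sampled points, both directions.
ellipse_boundary_gap <- function(e1, e2, n = 72) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  gap_dir <- function(ea, eb) {
    p <- ellipse_points(ea, tt)
    k <- eb$coef
    f <- conic_eval(eb, p)
    gu <- 2 * k[1] * p[, 1] + k[2] * p[, 2] + k[4]
    gv <- k[2] * p[, 1] + 2 * k[3] * p[, 2] + k[5]
    max(abs(f) / pmax(sqrt(gu^2 + gv^2), 1e-300))
  }
  max(gap_dir(e1, e2), gap_dir(e2, e1))
}

# Circular contour for the aligned case: the merged ellipse fitted to both
# rim images, plus its circle fit.
circular_lens <- function(e1, e2, n_points) {
  tt <- seq(0, 2 * pi, length.out = 65)[-65]
  merged <- tryCatch(
    fit_conic(rbind(ellipse_points(e1, tt), ellipse_points(e2, tt))),
    error = function(e) e1
  )
  if (is.null(merged$center_px)) merged <- e1
  ts <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  pts <- ellipse_points(merged, ts)
  ctr <- colMeans(pts)
  rad <- mean(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  lens_contour_object(
    pts, is_circular = TRUE, arc_conics = list(e1, e2),
    circle_fit = list(center_px = ctr, radius_px = rad)
  )
}

# ---- landmark sets ---------------------------------------------------------

#' Landmark set of one hole projection
#'
#' The significant landmarks used for pose matching: the two lens tips, the
#' apex of each arc (farthest arc point from the tip-to-tip chord) and two
#' quarter-points per arc (at half arc-length between tip and apex), plus the
#' per-arc conics. Aligned (round-appearing) holes instead carry a circle fit.
#'
#' @param tips 2 x 2 matrix (rows = tip points), or `NULL` when circular.
#' @param apexes 2 x 2 matrix (row i = apex of arc i), or `NULL`.
#' @param quarter_points 4 x 2 matrix (arc1 q1, arc1 q2, arc2 q1, arc2 q2).
#' @param arc_conics list of two [conic2d()] (or `NULL`).
#' @param is_circular logical.
#' @param circle_center_px,circle_radius_px circle fit when `is_circular`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(tips = NULL, apexes = NULL, quarter_points = NULL,
                         arc_conics = NULL, is_circular = FALSE,
                         circle_center_px = NULL, circle_radius_px = NULL) {
  structure(
    list(tips = tips, apexes = apexes, quarter_points = quarter_points,
         arc_conics = arc_conics, is_circular = is_circular,
         circle_center_px = circle_center_px,
         circle_radius_px = circle_radius_px),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  if (x$is_circular) {
    cat(sprintf("<landmark_set> circular: center (%.2f, %.2f), r %.2f px\n",
                x$circle_center_px[1], x$circle_center_px[2], x$circle_radius_px))
  } else {
    cat(sprintf("<landmark_set> 2 tips + 2 apexes + 4 quarter-points\n"))
  }
  invisible(x)
}

# Signed side of the directed chord t1 -> t2 on which point p lies.
chord_side <- function(t1, t2, p) {
  d <- t2 - t1
  sign(d[1] * (p[2] - t1[2]) - d[2] * (p[1] - t1[1]))
}

# Canonical ordering: tip order fixed by the dominant chord component being
# positive; arc 1 is the arc whose apex lies on the positive side of the
# directed chord; within each arc quarter-point 1 is on the tip-1 side.
# Detected and virtual sets pass through this same rule so that landmark
# vectors correspond element-wise.
canonicalize_landmarks <- function(ls) {
  if (ls$is_circular) return(ls)
  d <- ls$tips[2, ] - ls$tips[1, ]
  swap <- if (abs(d[1]) >= abs(d[2])) d[1] < 0 else d[2] < 0
  if (swap) {
    ls$tips <- ls$tips[2:1, , drop = FALSE]
    ls$quarter_points <- ls$quarter_points[c(2, 1, 4, 3), , drop = FALSE]
  }
  s1 <- chord_side(ls$tips[1, ], ls$tips[2, ], ls$apexes[1, ])
  if (s1 < 0) {
    ls$apexes <- ls$apexes[2:1, , drop = FALSE]
    ls$quarter_points <- ls$quarter_points[c(3, 4, 1, 2), , drop = FALSE]
    if (!is.null(ls$arc_conics)) ls$arc_conics <- ls$arc_conics[2:1]
  }
  ls
}

# Flatten to a residual vector: 16 numbers (lens) or 3 (circle).
landmark_vector <- function(ls) {
  if (ls$is_circular) {
    c(ls$circle_center_px, ls$circle_radius_px)
  } else {
    c(t(rbind(ls$tips, ls$apexes, ls$quarter_points)))
  }
}

# Apex of an elliptical arc: the arc point whose tangent is parallel to the
# tip-to-tip chord (arg-max of chord distance), found in closed form.
arc_apex <- function(conic, tt, chord_dir) {
  a <- conic$semi_axes_px[1]; b <- conic$semi_axes_px[2]
  th <- conic$orientation_rad
  u <- c(cos(th), sin(th)); w <- c(-sin(th), cos(th))
  dperp <- c(-chord_dir[2], chord_dir[1])
  t0 <- atan2(b * sum(w * dperp), a * sum(u * dperp))
  lo <- min(tt); hi <- max(tt)
  for (cand in c(t0, t0 + pi, t0 - pi, t0 + 2 * pi, t0 - 2 * pi)) {
    if (cand >= lo - 1e-9 && cand <= hi + 1e-9) {
      return(list(t = cand, point = as.numeric(ellipse_points(conic, cand))))
    }
  }
  # numerical fallback: maximize chord distance over the sampled parameters
  pts <- ellipse_points(conic, tt)
  p1 <- ellipse_points(conic, lo)
  dd <- abs((pts[, 1] - p1[1]) * chord_dir[2] - (pts[, 2] - p1[2]) * chord_dir[1])
  i <- which.max(dd)
  list(t = tt[i], point = pts[i, ])
}

# Arc-length midpoint between parameters ta and tb on an ellipse.
arc_halfway <- function(conic, ta, tb, n = 32) {
  tt <- seq(ta, tb, length.out = n)
  pts <- ellipse_points(conic, tt)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cs <- c(0, cumsum(seg))
  target <- cs[n] / 2
  i <- findInterval(target, cs, all.inside = TRUE)
  f <- (target - cs[i]) / max(cs[i + 1] - cs[i], 1e-300)
  t_half <- tt[i] + f * (tt[i + 1] - tt[i])
  as.numeric(ellipse_points(conic, t_half))
}

# Landmarks of one arc given its ellipse, tip parameters (monotone tt span)
# and the chord direction.
arc_landmarks <- function(conic, t_tip1, t_tip2, chord_dir) {
  tt <- seq(t_tip1, t_tip2, length.out = 64)
  apex <- arc_apex(conic, tt, chord_dir)
  q1 <- arc_halfway(conic, t_tip1, apex$t)
  q2 <- arc_halfway(conic, apex$t, t_tip2)
  list(apex = apex$point, quarters = rbind(q1, q2))
}

#' Virtual projection landmarks of a hole for a trial pose
#'
#' Runs the analytic forward model and applies the same landmark definitions
#' used on detected contours (tips, arc apexes, quarter-points; circle fit in
#' the aligned case), guaranteeing like-with-like correspondence during pose
#' optimization.
#'
#' @inheritParams lens_contour
#' @return A [landmark_set()].
#' @export
virtual_landmarks <- function(camera, nail, pose, hole_index) {
  rims <- hole_rim_circles(nail, pose, hole_index)
  e1 <- project_circle(camera, rims[[1]])
  e2 <- project_circle(camera, rims[[2]])
  circular <- ellipse_boundary_gap(e1, e2, n = 36) <= 1.0
  tips <- NULL
  if (!circular) {
    ix <- intersect_conics(e1, e2)
    if (ix$coincident || nrow(ix$points) == 0) {
      circular <- TRUE          # nested or coincident; separated handled below
      if (!ix$coincident &&
          !all(conic_eval(e2, ellipse_points(e1, seq(0, 2 * pi, length.out = 17))) < 0) &&
          !all(conic_eval(e1, ellipse_points(e2, seq(0, 2 * pi, length.out = 17))) < 0)) {
        empty_lens_error(hole_index)
      }
    } else {
      tips <- ix$points
      if (nrow(tips) > 2) {
        dmax <- -1; best <- c(1L, 2L)
        for (i in 1:(nrow(tips) - 1)) for (j in (i + 1):nrow(tips)) {
          d <- sum((tips[i, ] - tips[j, ])^2)
          if (d > dmax) { dmax <- d; best <- c(i, j) }
        }
        tips <- tips[best, , drop = FALSE]
      }
    }
  }
  if (circular) {
    cl <- circular_lens(e1, e2, 64)
    return(landmark_set(
      is_circular = TRUE, arc_conics = list(e1, e2),
      circle_center_px = cl$circle_fit$center_px,
      circle_radius_px = cl$circle_fit$radius_px
    ))
  }
  chord <- tips[2, ] - tips[1, ]
  # parameter spans of each arc, walked inside the other conic
  t1a <- ellipse_param_of(e1, tips[1, ]); t1b <- ellipse_param_of(e1, tips[2, ])
  t2a <- ellipse_param_of(e2, tips[1, ]); t2b <- ellipse_param_of(e2, tips[2, ])
  s1 <- sample_arc_inside(e1, t1a, t1b, e2, 3)
  s2 <- sample_arc_inside(e2, t2a, t2b, e1, 3)
  a1 <- arc_landmarks(e1, s1$t[1], s1$t[3], chord)
  a2 <- arc_landmarks(e2, s2$t[1], s2$t[3], chord)
  ls <- landmark_set(
    tips = tips,
    apexes = rbind(a1$apex, a2$apex),
    quarter_points = rbind(a1$quarters, a2$quarters),
    arc_conics = list(e1, e2)
  )
  canonicalize_landmarks(ls)
}
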