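# 6-DOF pose recovery of the distal nail segment from the landmark sets of
# both holes in a single projection.
#
# The single-view image of a circle of known radius admits two mirror 3D
# poses; each hole's rim pair therefore yields up to two hole-axis branches,
# and the joint two-hole solve disambiguates them by reprojection residual.
# Optimization is damped least squares (Levenberg-Marquardt) on an axis-angle
# increment composed onto the current rotation plus a translation in mm.

#' Pose solution container
#'
#' @param pose the recovered [nail_pose()].
#' @param rms_residual_px root-mean-square 2D landmark residual.
#' @param residuals_px per-landmark residual vector (pixel components).
#' @param branch_id which mirror-branch combination won (e.g. `"1-2"`).
#' @param converged logical.
#' @param iterations LM iterations spent.
#' @param covariance_diag diagonal of (J'J)^-1 (covariance proxy; rotation
#'   entries in rad^2, translation in mm^2).
#' @return An object of class `pose_solution`.
#' @export
pose_solution <- function(pose, rms_residual_px, residuals_px, branch_id,
                          converged, iterations, covariance_diag = NULL) {
  structure(
    list(pose = pose, rms_residual_px = rms_residual_px,
         residuals_px = residuals_px, branch_id = branch_id,
         converged = converged, iterations = iterations,
         covariance_diag = covariance_diag),
    class = "pose_solution"
  )
}

#' @export
print.pose_solution <- function(x, ...) {
  cat(sprintf(
    "<pose_solution> %s, rms %.4g px, branch %s, %d iterations\n",
    if (x$converged) "converged" else "NOT converged",
    x$rms_residual_px, x$branch_id, x$iterations
  ))
  invisible(x)
}

under_constrained_error <- function(msg) {
  stop(structure(
    class = c("nailguide_under_constrained", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Closed-form initial pose candidates from one hole's landmarks
#'
#' Recovers the circle pose of each fitted arc conic (two mirror solutions
#' each, depth fixed by the known rim radius), pairs the two rims' solutions
#' by axis agreement into at most two hole-axis branches, and promotes each
#' branch to a full nail pose (nail axis from the two detected hole centers
#' when both are available, or from the image's nail direction otherwise).
#'
#' @param landmarks a [landmark_set()] for the hole.
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param hole_index which hole the landmarks belong to (1 or 2).
#' @return list of candidate descriptors: each has `axis` (unit 3-vector),
#'   `center_mm` (hole center in camera frame) and `branch` (1 or 2).
#' @export
initial_pose_candidates <- function(landmarks, camera, nail, hole_index) {
  r_h <- nail$hole_radius_mm
  off <- rim_offset_mm(nail)
  if (landmarks$is_circular) {
    # aligned case: the hole axis is approximately the ray through the
    # circle-fit center; depth from the apparent radius (magnification)
    ctr <- landmarks$circle_center_px
    d <- unit3(as.numeric(pixel_to_ray(camera, ctr)))
    z <- r_h * camera$sdd_mm / (landmarks$circle_radius_px * camera$pixel_pitch_mm)
    depth <- z / d[3]
    return(list(list(axis = d, center_mm = d * depth, branch = 1L)))
  }
  safe_circle_poses <- function(conic) {
    if (is.null(conic) || is.null(conic$center_px)) return(NULL)
    tryCatch(circle_pose_candidates(camera, conic, r_h),
             error = function(e) NULL)
  }
  c1 <- safe_circle_poses(landmarks$arc_conics[[1]])
  c2 <- safe_circle_poses(landmarks$arc_conics[[2]])
  out <- list()
  if (!is.null(c1) && !is.null(c2)) {
    for (b in seq_along(c1)) {
      a1 <- c1[[b]]
      # partner rim: mirror whose axis direction agrees best (as a line)
      agree <- vapply(c2, function(cc) abs(sum(cc$normal * a1$normal)), numeric(1))
      a2 <- c2[[which.max(agree)]]
      axis <- unit3(a1$normal + sign(sum(a1$normal * a2$normal)) * a2$normal)
      center <- (a1$center_mm + a2$center_mm) / 2
      out[[length(out) + 1L]] <- list(axis = axis, center_mm = center,
                                      branch = as.integer(b))
    }
  } else if (!is.null(c1) || !is.null(c2)) {
    # one usable rim conic: its circle is one rim; the hole center sits half
    # a channel away along the axis, sign unknown
    cs <- if (is.null(c1)) c2 else c1
    for (b in seq_along(cs)) {
      for (sgn in c(1, -1)) {
        out[[length(out) + 1L]] <- list(
          axis = cs[[b]]$normal,
          center_mm = cs[[b]]$center_mm + sgn * off * cs[[b]]$normal,
          branch = as.integer(b))
      }
    }
  }
  # always append shape-based candidates: obliquity and magnification solved
  # from the lens tip-to-tip length and width (robust to poor arc conics)
  shp <- tryCatch(lens_shape_candidates(landmarks, camera, nail),
                  error = function(e) NULL)
  if (!is.null(shp)) {
    for (s in shp) out[[length(out) + 1L]] <- s
  }
  if (!length(out)) {
    # last resort: crude centroid/extent fallback (aligned-style)
    pts <- rbind(landmarks$tips, landmarks$apexes)
    ctr <- colMeans(pts)
    d <- unit3(as.numeric(pixel_to_ray(camera, ctr)))
    app_r <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
    z <- r_h * camera$sdd_mm / max(app_r * camera$pixel_pitch_mm, 1e-6)
    out <- list(list(axis = d, center_mm = d * (z / d[3]), branch = 1L))
  }
  out
}

# Obliquity theta and magnification from the lens dimensions: with rim radius
# r_h and rim offset h (= sqrt(R^2 - r_h^2)), the half tip-to-tip length is
# m r_h sqrt(1 - (h/r_h)^2 tan^2 theta) and the half width is
# m (r_h cos theta - h sin theta); their ratio fixes theta, then m fixes the
# depth of the hole center along the centroid ray. The in-plane tilt
# direction is perpendicular to the tip chord; its sign is the mirror
# ambiguity, so both candidates are returned.
lens_shape_candidates <- function(landmarks, camera, nail) {
  if (landmarks$is_circular) return(NULL)
  r_h <- nail$hole_radius_mm
  hoff <- rim_offset_mm(nail)
  k <- hoff / r_h
  t1 <- landmarks$tips[1, ]; t2 <- landmarks$tips[2, ]
  ctr <- (t1 + t2) / 2
  ell2 <- sqrt(sum((t2 - t1)^2)) / 2
  w2 <- mean(chord_distance(landmarks$apexes, t1, t2))
  ratio <- ell2 / max(w2, 1e-9)
  th_max <- atan(1 / k)
  g <- function(th) {
    num <- r_h * sqrt(max(1 - k^2 * tan(th)^2, 1e-12))
    den <- r_h * cos(th) - hoff * sin(th)
    num / max(den, 1e-12) - ratio
  }
  if (g(1e-4) > 0) {
    theta <- 1e-3
  } else {
    theta <- stats::uniroot(g, c(1e-4, th_max * 0.999), tol = 1e-10)$root
  }
  m1 <- ell2 / (r_h * sqrt(max(1 - k^2 * tan(theta)^2, 1e-12)))
  m2 <- w2 / max(r_h * cos(theta) - hoff * sin(theta), 1e-12)
  m <- (m1 + m2) / 2
  z <- camera$sdd_mm / (m * camera$pixel_pitch_mm)
  v <- unit3(as.numeric(pixel_to_ray(camera, ctr)))
  center <- v * (z / v[3])
  chord <- (t2 - t1) / max(sqrt(sum((t2 - t1)^2)), 1e-12)
  pd <- c(-chord[2], chord[1])
  w3 <- unit3(c(pd[1], pd[2], 0) - sum(c(pd[1], pd[2], 0) * v) * v)
  lapply(1:2, function(b) {
    sgn <- c(1, -1)[b]
    list(axis = unit3(cos(theta) * v + sgn * sin(theta) * w3),
         center_mm = center, branch = b)
  })
}

# Build a full nail pose from per-hole axis/center estimates of both holes.
# The per-hole depth estimates carry most of the initialization error and the
# nail-axis direction is hypersensitive to their difference, so the centers
# are first rescaled to a common depth and that depth is corrected using the
# known axial separation of the two holes.
candidate_to_pose <- function(cand1, cand2, nail) {
  st <- vapply(nail$holes, function(h) h$axial_station_mm, numeric(1))
  z1 <- cand1$center_mm[3]; z2 <- cand2$center_mm[3]
  if (z1 <= 0 || z2 <= 0) return(NULL)
  zbar <- (z1 + z2) / 2
  p1 <- cand1$center_mm * (zbar / z1)
  p2 <- cand2$center_mm * (zbar / z2)
  sep <- sqrt(sum((p2 - p1)^2))
  if (sep < 1e-6) return(NULL)
  scale <- abs(st[2] - st[1]) / sep
  scale <- min(max(scale, 0.7), 1.3)
  cand1 <- list(axis = cand1$axis, center_mm = p1 * scale)
  cand2 <- list(axis = cand2$axis, center_mm = p2 * scale)
  zc <- unit3((cand2$center_mm - cand1$center_mm) * sign(st[2] - st[1]))
  poses <- list()
  for (sgn in c(1, -1)) {
    a0 <- sgn * cand1$axis
    x_img <- a0 - sum(a0 * zc) * zc
    if (sqrt(sum(x_img^2)) < 1e-9) next
    x_img <- unit3(x_img)
    # rotation mapping hole-1 axis direction (nail frame) to x_img and the
    # nail axis to zc
    a_n <- nail$holes[[1]]$axis_dir_nail_frame
    Rn <- cbind(a_n, crossprod3(c(0, 0, 1), a_n), c(0, 0, 1))
    Rc <- cbind(x_img, crossprod3(zc, x_img), zc)
    R <- Rc %*% t(Rn)
    t1 <- cand1$center_mm - as.numeric(R %*% c(0, 0, st[1]))
    poses[[length(poses) + 1L]] <-
      list(pose = nail_pose(R, t1),
           axis2_fit = abs(sum((R %*% nail$holes[[2]]$axis_dir_nail_frame) *
                                 cand2$axis)))
  }
  if (!length(poses)) return(NULL)
  fits <- vapply(poses, function(p) p$axis2_fit, numeric(1))
  # for parallel layouts both signs fit equally; keep both as candidates
  if (abs(diff(range(fits))) < 1e-6 && length(poses) == 2) {
    lapply(poses, `[[`, "pose")
  } else {
    list(poses[[which.max(fits)]]$pose)
  }
}

# Residual vector between detected landmark sets and the virtual landmarks
# of a trial pose. Detected tips/arcs are matched to virtual ones by
# proximity (tip permutation) and side-of-chord sign via canonical ordering.
pose_residual <- function(pose, detected, camera, nail, holes) {
  res <- numeric(0)
  for (i in seq_along(holes)) {
    det <- detected[[i]]
    vl <- tryCatch(
      virtual_landmarks(camera, nail, pose, holes[i]),
      error = function(e) NULL
    )
    if (is.null(vl)) return(NULL)
    if (det$is_circular != vl$is_circular) {
      # mixed regimes near the circularity boundary: compare circle summaries
      det_c <- landmark_circle_summary(det)
      vl_c <- landmark_circle_summary(vl)
      res <- c(res, det_c - vl_c)
      next
    }
    if (det$is_circular) {
      res <- c(res, c(det$circle_center_px - vl$circle_center_px,
                      det$circle_radius_px - vl$circle_radius_px))
    } else {
      vv <- landmark_vector(vl)
      dv <- landmark_vector(det)
      # guard against a tip-order flip between the two canonical orderings
      if (sum((dv[1:4] - vv[c(3, 4, 1, 2)])^2) < sum((dv[1:4] - vv[1:4])^2)) {
        vv <- landmark_vector(flip_landmark_order(vl))
      }
      res <- c(res, dv - vv)
    }
  }
  res
}

landmark_circle_summary <- function(ls) {
  if (ls$is_circular) {
    c(ls$circle_center_px, ls$circle_radius_px)
  } else {
    ctr <- colMeans(rbind(ls$tips, ls$apexes))
    rad <- mean(sqrt(rowSums(sweep(rbind(ls$tips, ls$apexes), 2, ctr)^2)))
    c(ctr, rad)
  }
}

flip_landmark_order <- function(ls) {
  ls$tips <- ls$tips[2:1, , drop = FALSE]
  ls$quarter_points <- ls$quarter_points[c(2, 1, 4, 3), , drop = FALSE]
  s1 <- chord_side(ls$tips[1, ], ls$tips[2, ], ls$apexes[1, ])
  if (s1 < 0) {
    ls$apexes <- ls$apexes[2:1, , drop = FALSE]
    ls$quarter_points <- ls$quarter_points[c(3, 4, 1, 2), , drop = FALSE]
  }
  ls
}

# Levenberg-Marquardt refinement of a pose against detected landmarks.
lm_refine <- function(pose, detected, camera, nail, holes,
                      max_iter = 200L, grad_tol = 1e-10, step_tol = 1e-12) {
  theta <- c(0, 0, 0, pose$translation_mm)
  R0 <- pose$rotation
  make_pose <- function(th) {
    nail_pose(axis_angle_to_rotation(th[1:3]) %*% R0, th[4:6])
  }
  r <- pose_residual(make_pose(theta), detected, camera, nail, holes)
  if (is.null(r)) return(NULL)
  cost <- sum(r^2)
  lambda <- 1e-3
  n_iter <- 0L
  converged <- FALSE
  trace_cost <- cost
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # forward-difference Jacobian in the 6 local parameters
    J <- matrix(0, length(r), 6)
    eps <- c(rep(1e-6, 3), rep(1e-4, 3))
    ok <- TRUE
    for (j in 1:6) {
      th <- theta
      th[j] <- th[j] + eps[j]
      rj <- pose_residual(make_pose(th), detected, camera, nail, holes)
      if (is.null(rj) || length(rj) != length(r)) { ok <- FALSE; break }
      J[, j] <- (rj - r) / eps[j]
    }
    if (!ok) break
    g <- crossprod(J, r)
    if (max(abs(g)) < grad_tol) { converged <- TRUE; break }
    H <- crossprod(J)
    improved <- FALSE
    for (try in 1:12) {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12), -g),
        error = function(e) NULL
      )
      if (is.null(step)) { lambda <- lambda * 10; next }
      th_new <- theta + as.numeric(step)
      r_new <- pose_residual(make_pose(th_new), detected, camera, nail, holes)
      if (!is.null(r_new) && length(r_new) == length(r) &&
          sum(r_new^2) < cost) {
        # accept: fold the rotation increment into the reference rotation
        p_new <- make_pose(th_new)
        R0 <- p_new$rotation
        theta <- c(0, 0, 0, th_new[4:6])
        r <- r_new
        cost <- sum(r^2)
        trace_cost <- c(trace_cost, cost)
        lambda <- max(lambda / 3, 1e-12)
        improved <- TRUE
        if (sqrt(sum(step^2)) < step_tol) converged <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (!improved) {
      # damping drove the step below resolution: treat the stall as the
      # step-size termination criterion (residual is at its floor)
      converged <- is.finite(cost)
      break
    }
    if (converged) break
    if (cost < 1e-24) { converged <- TRUE; break }
  }
  H <- tryCatch(crossprod(J), error = function(e) NULL)
  cov_diag <- if (!is.null(H)) {
    hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(hi)) diag(hi) else rep(NA_real_, 6)
  } else rep(NA_real_, 6)
  list(pose = make_pose(theta), residuals = r,
       rms = sqrt(mean(r^2)), converged = converged,
       iterations = n_iter, cov_diag = cov_diag, trace_cost = trace_cost)
}

#' Solve the 6-DOF nail pose from both holes' landmarks
#'
#' Enumerates the mirror-branch candidate combinations from
#' [initial_pose_candidates()], pre-polishes each with a short damped
#' least-squares pass, fully refines the best few and returns the
#' lowest-residual converged solution. Hole-axis signs are chosen so the
#' drill entry side faces the X-ray source.
#'
#' @param landmarks_both list of two [landmark_set()] (hole 1, hole 2); one
#'   element may be `NULL`, which raises an under-constrained signal.
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param init_poses optional list of [nail_pose()] to use as starting points
#'   instead of the closed-form candidates.
#' @return A [pose_solution()].
#' @export
solve_pose <- function(landmarks_both, camera, nail, init_poses = NULL) {
  stopifnot(length(landmarks_both) == 2L)
  missing_hole <- vapply(landmarks_both, is.null, logical(1))
  if (all(missing_hole)) under_constrained_error("no landmarks for either hole")
  if (any(missing_hole)) {
    k <- which(!missing_hole)
    h <- nail$holes[[k]]
    under_constrained_error(sprintf(
      paste0("only hole %d is constrained: the rotation about its hole axis ",
             "(%s direction) is free; a single hole cannot fix all 6 DOF"),
      k, h$label))
  }
  detected <- landmarks_both
  holes <- c(1L, 2L)

  cand_poses <- list()
  if (!is.null(init_poses)) {
    cand_poses <- lapply(init_poses, function(p) list(pose = p, branch = "init"))
  } else {
    cands1 <- initial_pose_candidates(detected[[1]], camera, nail, 1L)
    cands2 <- initial_pose_candidates(detected[[2]], camera, nail, 2L)
    for (i in seq_along(cands1)) for (j in seq_along(cands2)) {
      ps <- candidate_to_pose(cands1[[i]], cands2[[j]], nail)
      if (is.null(ps)) next
      for (k in seq_along(ps)) {
        cand_poses[[length(cand_poses) + 1L]] <-
          list(pose = ps[[k]],
               branch = sprintf("%d-%d%s", i, j,
                                if (length(ps) > 1) c("a", "b")[k] else ""))
      }
    }
  }
  if (!length(cand_poses)) {
    return(pose_solution(NULL, Inf, numeric(0), "none", FALSE, 0L))
  }

  # collapse near-duplicate candidates (the per-hole candidate sources often
  # agree) and cap the enumeration
  keep_cand <- list()
  for (cp in cand_poses) {
    dup <- FALSE
    for (kc in keep_cand) {
      dr <- max(abs(cp$pose$rotation - kc$pose$rotation))
      dt <- max(abs(cp$pose$translation_mm - kc$pose$translation_mm))
      if (dr < 0.02 && dt < 2) { dup <- TRUE; break }
    }
    if (!dup) keep_cand[[length(keep_cand) + 1L]] <- cp
    if (length(keep_cand) >= 12L) break
  }
  cand_poses <- keep_cand

  # cheap pre-pass on every branch combination, full refinement of the best 3
  pre <- lapply(cand_poses, function(cp) {
    lm_refine(cp$pose, detected, camera, nail, holes, max_iter = 4L)
  })
  keep <- which(!vapply(pre, is.null, logical(1)))
  if (!length(keep)) {
    return(pose_solution(NULL, Inf, numeric(0), "none", FALSE, 0L))
  }
  ord <- keep[order(vapply(pre[keep], function(p) p$rms, numeric(1)))]
  ord <- ord[seq_len(min(3L, length(ord)))]
  best <- NULL; best_branch <- "none"; best_iter <- 0L
  for (i in ord) {
    ref <- lm_refine(pre[[i]]$pose, detected, camera, nail, holes)
    if (is.null(ref)) next
    ref$iterations <- ref$iterations + pre[[i]]$iterations
    if (ref$converged && (is.null(best) || ref$rms < best$rms)) {
      best <- ref
      best_branch <- cand_poses[[i]]$branch
    }
  }
  if (is.null(best)) {
    # fall back to the best non-converged refinement for diagnostics
    i <- ord[1]
    ref <- lm_refine(pre[[i]]$pose, detected, camera, nail, holes)
    return(pose_solution(if (is.null(ref)) NULL else ref$pose,
                         if (is.null(ref)) Inf else ref$rms,
                         if (is.null(ref)) numeric(0) else ref$residuals,
                         cand_poses[[i]]$branch, FALSE,
                         if (is.null(ref)) 0L else ref$iterations))
  }
  pose_solution(best$pose, best$rms, best$residuals, best_branch,
                TRUE, best$iterations, best$cov_diag)
}

#' Simulate the not-yet-drilled hole from a previous solution
#'
#' After the first screw is inserted, its hole is occluded and a fresh solve
#' is impossible; the second hole is instead forward-projected from the prior
#' pose, optionally corrected for inter-frame patient/C-arm shifts by a
#' translation (from [estimate_frame_shift()]) applied to all projected
#' landmarks.
#'
#' @param prior a converged [pose_solution()].
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param hole_index the hole to simulate.
#' @param shift_px optional length-2 pixel shift `(du, dv)` to apply.
#' @return list with `landmarks` (shifted [landmark_set()]) and `shift_px`.
#' @export
simulate_second_hole <- function(prior, camera, nail, hole_index,
                                 shift_px = c(0, 0)) {
  if (!inherits(prior, "pose_solution") || !isTRUE(prior$converged)) {
    stop("prior pose solution has not converged")
  }
  vl <- virtual_landmarks(camera, nail, prior$pose, hole_index)
  list(landmarks = shift_landmarks(vl, shift_px), shift_px = shift_px)
}

shift_landmarks <- function(ls, shift_px) {
  sh <- function(m) if (is.null(m)) NULL else sweep(m, 2, shift_px, "+")
  ls$tips <- sh(ls$tips)
  ls$apexes <- sh(ls$apexes)
  ls$quarter_points <- sh(ls$quarter_points)
  if (!is.null(ls$circle_center_px)) {
    ls$circle_center_px <- ls$circle_center_px + shift_px
  }
  if (!is.null(ls$arc_conics)) {
    ls$arc_conics <- lapply(ls$arc_conics, function(cc) {
      if (is.null(cc) || is.null(cc$center_px)) return(cc)
      ellipse_conic(cc$center_px + shift_px, cc$semi_axes_px, cc$orientation_rad)
    })
  }
  ls
}

# Error metrics of a solved pose against ground truth, reported per hole as
# undirected axis angle (deg) and center distance (mm). The nail solid is
# invariant under a half-turn about its axis, so these per-hole line/point
# metrics are the identifiable quantities.
pose_error_metrics <- function(solved_pose, true_pose, nail) {
  axes <- centers <- numeric(2)
  for (k in 1:2) {
    s <- hole_axis_camera(nail, solved_pose, k)
    g <- hole_axis_camera(nail, true_pose, k)
    axes[k] <- line_angle_deg(s$axis, g$axis)
    centers[k] <- sqrt(sum((s$center - g$center)^2))
  }
  list(axis_deg = axes, center_mm = centers)
}
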