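# Detection of the lens-shaped hole projections and extraction of the
# significant contour landmarks.

no_hole_error <- function() {
  stop(structure(
    class = c("nailguide_no_hole", "error", "condition"),
    list(message = "no hole projection found in the image", call = NULL)
  ))
}

ambiguity_error <- function(candidates) {
  stop(structure(
    class = c("nailguide_ambiguity", "error", "condition"),
    list(message = sprintf(
      "ambiguous detection: %d candidate hole projections", length(candidates)),
      call = NULL, candidates = candidates)
  ))
}

occluded_hole_warning <- function() {
  warning(structure(
    class = c("nailguide_occluded_hole", "warning", "condition"),
    list(message = "only one open hole projection found (screw inserted in the other?)",
         call = NULL)
  ))
}

#' Detect lens-shaped hole projections in a radiograph
#'
#' Finds the dark nail silhouette (Otsu threshold + largest connected
#' component), thresholds the bright regions enclosed by it, filters the
#' candidates by area and solidity and traces each survivor's boundary at
#' subpixel precision with marching squares on the Gaussian-smoothed image
#' (iso-level halfway between region and surround intensity). Candidates are
#' ordered along the nail axis direction.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param camera a [camera_model()] (used for sanity checks only; detection
#'   itself is calibration-free).
#' @param min_area_px minimum candidate area in px^2.
#' @param min_solidity minimum area / convex hull area.
#' @param smooth_sigma Gaussian smoothing sigma in px.
#' @return list of up to two [lens_contour_object()] (tips not yet assigned).
#'   Raises a `nailguide_no_hole` error when nothing is found, a
#'   `nailguide_ambiguity` error (carrying all candidates) when more than two
#'   survive, and signals a `nailguide_occluded_hole` warning when only one
#'   hole is visible.
#' @export
detect_lens_regions <- function(image, camera = NULL, min_area_px = 30,
                                min_solidity = 0.85, smooth_sigma = 1) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (!all(is.finite(rng))) stop("image contains non-finite values")
  img <- if (rng[2] > 1 || rng[1] < 0) (image - rng[1]) / (rng[2] - rng[1]) else image
  sm <- gaussian_smooth(img, smooth_sigma)
  attr(sm, "raw") <- img

  thr <- otsu_threshold(as.vector(sm))
  dark <- sm < thr
  if (!any(dark)) no_hole_error()
  lab <- label_components(dark)
  sizes <- tabulate(lab[lab > 0])
  sil <- lab == which.max(sizes)

  # bright regions enclosed by the silhouette: components of the complement
  # that do not touch the image border and neighbor the silhouette
  comp <- label_components(!sil)
  border_ids <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
  border_ids <- border_ids[border_ids > 0]
  enclosed_ids <- setdiff(unique(comp[comp > 0]), border_ids)
  if (!length(enclosed_ids)) no_hole_error()

  cands <- list()
  for (id in enclosed_ids) {
    px <- which(comp == id, arr.ind = TRUE)       # (v+1, u+1)
    area <- nrow(px)
    if (area < min_area_px) next
    uv <- cbind(px[, 2] - 1, px[, 1] - 1)
    sol <- area / max(hull_area(uv), 1)
    if (sol < min_solidity) next
    cands[[length(cands) + 1L]] <- list(px = px, uv = uv, area = area)
  }
  if (!length(cands)) no_hole_error()
  if (length(cands) > 2L) {
    traced <- lapply(cands, function(cd) trace_region_contour(sm, sil, cd))
    ambiguity_error(Filter(Negate(is.null), traced))
  }

  # order along the nail axis: principal direction of the silhouette pixels
  sil_px <- which(sil, arr.ind = TRUE)
  sil_uv <- cbind(sil_px[, 2] - 1, sil_px[, 1] - 1)
  ax <- eigen(stats::cov(sil_uv), symmetric = TRUE)$vectors[, 1]
  proj <- vapply(cands, function(cd) sum(colMeans(cd$uv) * ax), numeric(1))
  cands <- cands[order(proj)]

  out <- lapply(cands, function(cd) trace_region_contour(sm, sil, cd))
  out <- Filter(Negate(is.null), out)
  if (!length(out)) no_hole_error()
  if (length(out) == 1L) occluded_hole_warning()
  out
}

# Subpixel boundary of one candidate region: marching squares at the
# mid-level between region interior and dark surround, on a local window.
trace_region_contour <- function(sm, sil, cand) {
  h <- nrow(sm); w <- ncol(sm)
  v0 <- max(min(cand$px[, 1]) - 6L, 1L); v1 <- min(max(cand$px[, 1]) + 6L, h)
  u0 <- max(min(cand$px[, 2]) - 6L, 1L); u1 <- min(max(cand$px[, 2]) + 6L, w)
  win <- sm[v0:v1, u0:u1, drop = FALSE]
  # mid-level of the local edge contrast, measured on the un-blurred image so
  # that the narrow lens plateau and the blurred silhouette halo do not drag
  # the level (and thus the subpixel contour) outward
  raw <- attr(sm, "raw")
  if (is.null(raw)) raw <- sm
  inside <- raw[cand$px]
  ring <- sil[v0:v1, u0:u1, drop = FALSE]
  surround <- raw[v0:v1, u0:u1, drop = FALSE][ring]
  if (!length(surround)) surround <- min(win)
  level <- 0.5 * (stats::median(inside) + stats::median(surround))
  loops <- iso_contours(win, level)
  ctr <- colMeans(cand$uv)
  ctr_local <- c(ctr[1] - (u0 - 1L), ctr[2] - (v0 - 1L))
  best <- NULL
  for (lp in loops) {
    if (!lp$closed || nrow(lp$points) < 8) next
    if (point_in_polygon(ctr_local, lp$points)) {
      if (is.null(best) || nrow(lp$points) > nrow(best)) best <- lp$points
    }
  }
  if (is.null(best)) return(NULL)
  best <- refine_contour_gradient(win, best)
  pts <- cbind(best[, 1] + (u0 - 1L), best[, 2] + (v0 - 1L))
  lens_contour_object(pts)
}

# Bilinear sampling of an image at 0-based (u, v) points.
bilinear_sample <- function(img, uv) {
  h <- nrow(img); w <- ncol(img)
  u <- pmin(pmax(uv[, 1], 0), w - 1.001)
  v <- pmin(pmax(uv[, 2], 0), h - 1.001)
  u0 <- floor(u); v0 <- floor(v)
  fu <- u - u0; fv <- v - v0
  i00 <- cbind(v0 + 1, u0 + 1); i01 <- cbind(v0 + 1, u0 + 2)
  i10 <- cbind(v0 + 2, u0 + 1); i11 <- cbind(v0 + 2, u0 + 2)
  img[i00] * (1 - fu) * (1 - fv) + img[i01] * fu * (1 - fv) +
    img[i10] * (1 - fu) * fv + img[i11] * fu * fv
}

# Subpixel refinement of contour points to the gradient-magnitude maximum
# along the local normal (the gradient peak of a blurred step edge sits on
# the true edge, independent of the iso level used for tracing).
refine_contour_gradient <- function(win, pts, reach = 1.5) {
  h <- nrow(win); w <- ncol(win)
  gu <- (win[, c(2:w, w)] - win[, c(1, 1:(w - 1))]) / 2
  gv <- (win[c(2:h, h), ] - win[c(1, 1:(h - 1)), ]) / 2
  gm <- sqrt(gu^2 + gv^2)
  n <- nrow(pts)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  tg <- pts[ip, ] - pts[im, ]
  tn <- sqrt(rowSums(tg^2))
  nrm <- cbind(-tg[, 2], tg[, 1]) / pmax(tn, 1e-300)
  ts <- seq(-reach, reach, by = 0.5)
  prof <- vapply(ts, function(t) {
    bilinear_sample(gm, pts + t * nrm)
  }, numeric(n))
  imax <- max.col(prof, ties.method = "first")
  delta <- ts[imax]
  # parabolic sub-step around the discrete maximum
  inner <- imax > 1 & imax < length(ts)
  if (any(inner)) {
    i <- which(inner)
    y0 <- prof[cbind(i, imax[i] - 1L)]
    y1 <- prof[cbind(i, imax[i])]
    y2 <- prof[cbind(i, imax[i] + 1L)]
    den <- y0 - 2 * y1 + y2
    adj <- ifelse(abs(den) > 1e-12, 0.25 * (y0 - y2) / den, 0)
    delta[i] <- delta[i] + pmin(pmax(adj, -0.25), 0.25)
  }
  pts + delta * nrm
}

# ---- landmark extraction ---------------------------------------------------

# Kasa algebraic circle fit.
circle_fit_kasa <- function(pts) {
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- qr.solve(A, b)
  list(center_px = sol[1:2], radius_px = sqrt(sol[3] + sum(sol[1:2]^2)))
}

# Resample a closed polyline to n points of uniform arc length.
resample_closed <- function(pts, n = 256L) {
  p <- rbind(pts, pts[1, ])
  seg <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  cs <- c(0, cumsum(seg))
  total <- cs[length(cs)]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  i <- findInterval(s, cs, all.inside = TRUE)
  f <- (s - cs[i]) / pmax(cs[i + 1] - cs[i], 1e-300)
  cbind(p[i, 1] + f * (p[i + 1, 1] - p[i, 1]),
        p[i, 2] + f * (p[i + 1, 2] - p[i, 2]))
}

# Circular moving average of the rows of a closed contour.
smooth_closed <- function(pts, k = 2L) {
  n <- nrow(pts)
  out <- pts * 0
  wsum <- 2 * k + 1
  for (d in -k:k) {
    idx <- ((seq_len(n) - 1 + d) %% n) + 1
    out <- out + pts[idx, ]
  }
  out / wsum
}

# Discrete curvature of a closed contour (unsigned).
contour_curvature <- function(pts) {
  n <- nrow(pts)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  d1 <- (pts[ip, ] - pts[im, ]) / 2
  d2 <- pts[ip, ] - 2 * pts + pts[im, ]
  cr <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  abs(cr) / pmax((d1[, 1]^2 + d1[, 2]^2)^1.5, 1e-300)
}

# Index (with wraparound distance) utilities on a closed contour.
circ_dist <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

# Split closed contour indices into the two arcs between tips i1 < i2.
split_arcs <- function(n, i1, i2) {
  if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
  list(seq(i1, i2), c(seq(i2, n), seq(1, i1)))
}

# Distance of points from the infinite chord through t1 -> t2.
chord_distance <- function(pts, t1, t2) {
  d <- t2 - t1
  dn <- sqrt(sum(d^2))
  abs((pts[, 1] - t1[1]) * d[2] - (pts[, 2] - t1[2]) * d[1]) / max(dn, 1e-300)
}

# Arc-length halfway point between two indices along an open polyline chain.
polyline_halfway <- function(pts) {
  if (nrow(pts) < 2) return(as.numeric(pts[1, ]))
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  cs <- c(0, cumsum(seg))
  target <- cs[length(cs)] / 2
  i <- findInterval(target, cs, all.inside = TRUE)
  f <- (target - cs[i]) / max(cs[i + 1] - cs[i], 1e-300)
  as.numeric(pts[i, ] + f * (pts[i + 1, ] - pts[i, ]))
}

#' Extract significant landmarks from a lens contour
#'
#' Locates the two tips (initialized at the contour's diameter endpoints,
#' polished by local chord-line intersection at sharp corners or by the
#' crossing of a jointly fitted rim-image ellipse pair at blur-rounded
#' corners), splits the contour into its two arcs, fits the per-arc conics,
#' and derives each arc's apex (farthest point from the tip-to-tip chord)
#' plus two quarter-points (half arc-length between tip and apex). Contours
#' whose curvature contrast is below `circular_contrast` times the median
#' curvature are classified round-appearing and summarized by a
#' least-squares circle fit instead.
#'
#' @param contour a [lens_contour_object()] with at least 20 points.
#' @param circular_contrast curvature contrast threshold for the circular
#'   degeneracy rule.
#' @param rim_ratio rim-plane offset over hole radius of the nail
#'   (`sqrt(R^2 - r_h^2) / r_h`), coupling the rim-image pair model; default
#'   matches the standard 10 mm nail with 4 mm holes.
#' @return A [landmark_set()].
#' @export
extract_landmarks <- function(contour, circular_contrast = 3,
                              rim_ratio = sqrt(21) / 2) {
  pts <- contour$points
  if (nrow(pts) < 20L) stop("contour has fewer than 20 points")
  if (anyDuplicated(round(pts, 9)) &&
      sum(duplicated(round(pts, 9))) > nrow(pts) / 4) {
    stop("contour is degenerate (many duplicate points)")
  }
  n <- 256L
  rs <- resample_closed(pts, n)
  rs_sm <- smooth_closed(rs, k = 3L)
  kappa <- contour_curvature(rs_sm)
  if (max(kappa) < circular_contrast * stats::median(kappa)) {
    cf <- circle_fit_kasa(pts)
    return(landmark_set(is_circular = TRUE,
                        circle_center_px = cf$center_px,
                        circle_radius_px = cf$radius_px))
  }

  # initial tips: the diameter endpoints of the contour (robust to point
  # noise, unlike raw curvature maxima); the lens is elongated tip-to-tip
  D2 <- outer(rs_sm[, 1], rs_sm[, 1], "-")^2 +
    outer(rs_sm[, 2], rs_sm[, 2], "-")^2
  ij <- which(D2 == max(D2), arr.ind = TRUE)[1, ]
  i1 <- ij[1]; i2 <- ij[2]
  arcs <- split_arcs(n, i1, i2)
  interior <- function(idx) {
    m <- length(idx)
    trim <- max(2L, round(0.12 * m))
    rs[idx[(trim + 1):(m - trim)], , drop = FALSE]
  }

  # rim-image model fit: weak-perspective twin fit always (also used as the
  # initializer), upgraded to the exact projective rim-pair fit when the
  # camera and nail geometry are known
  tw <- tryCatch(
    fit_twin_ellipses(interior(arcs[[1]]), interior(arcs[[2]]), k2 = rim_ratio),
    error = function(e) NULL)
  f1 <- f2 <- NULL
  if (!is.null(tw)) { f1 <- tw$e1; f2 <- tw$e2 }
  if (is.null(f1) || is.null(f2)) {
    arc_conic <- function(idx) {
      use <- interior(idx)
      if (nrow(use) < 8) return(NULL)
      tryCatch(fit_conic(use), error = function(e) NULL)
    }
    f1 <- arc_conic(arcs[[1]])
    f2 <- arc_conic(arcs[[2]])
  }
  cx <- NULL
  if (!is.null(f1) && !is.null(f2) &&
      !is.null(f1$center_px) && !is.null(f2$center_px)) {
    ix <- tryCatch(intersect_conics(f1, f2), error = function(e) NULL)
    if (!is.null(ix) && !ix$coincident && nrow(ix$points) >= 2) cx <- ix$points
  }

  # per-tip refinement: a sharp corner (analytic contour, crisp trace) is
  # kept and polished by intersecting local chord lines; a blur-rounded
  # corner is replaced by the fitted rim-model crossing
  tips <- rs[c(i1, i2), , drop = FALSE]
  for (k in 1:2) {
    i0 <- c(i1, i2)[k]
    if (vertex_turn_deg(rs, i0) > 20) {
      tp <- refine_tip_lines(rs, i0)
      if (!is.null(tp)) tips[k, ] <- tp
    } else if (!is.null(cx)) {
      dd <- rowSums(sweep(cx, 2, tips[k, ])^2)
      if (min(dd) < 36) tips[k, ] <- cx[which.min(dd), ]
    }
  }

  # re-split the resampled contour at the refined tips; both arcs are walked
  # tip 1 -> tip 2 so quarter-point 1 always sits on the tip-1 side
  j1 <- which.min(rowSums(sweep(rs, 2, tips[1, ])^2))
  j2 <- which.min(rowSums(sweep(rs, 2, tips[2, ])^2))
  if (j1 == j2) stop("degenerate contour: tips coincide")
  o <- ((j1 - 1 + 0:(n - 1)) %% n) + 1
  p2 <- which(o == j2)
  arc_fwd <- o[1:p2]
  arc_bwd <- rev(c(o[p2:n], j1))
  arc_landmarks_detected <- function(idx) {
    ap <- rs[idx, , drop = FALSE]
    ap[1, ] <- tips[1, ]; ap[nrow(ap), ] <- tips[2, ]
    dd <- chord_distance(ap, tips[1, ], tips[2, ])
    ia <- which.max(dd)
    apex <- refine_apex(ap, ia, tips[1, ], tips[2, ])
    q1 <- polyline_halfway(ap[seq(1, ia), , drop = FALSE])
    q2 <- polyline_halfway(ap[seq(ia, nrow(ap)), , drop = FALSE])
    list(apex = apex, quarters = rbind(q1, q2))
  }
  a1 <- arc_landmarks_detected(arc_fwd)
  a2 <- arc_landmarks_detected(arc_bwd)
  ls <- landmark_set(
    tips = tips,
    apexes = rbind(a1$apex, a2$apex),
    quarter_points = rbind(a1$quarters, a2$quarters),
    arc_conics = list(f1, f2)
  )
  canonicalize_landmarks(ls)
}

# Turn angle (degrees) of the contour at vertex i over a +/-3 sample window.
vertex_turn_deg <- function(rs, i) {
  n <- nrow(rs)
  a <- rs[((i - 1 - 3) %% n) + 1, ]
  b <- rs[i, ]
  d <- rs[((i - 1 + 3) %% n) + 1, ]
  v1 <- b - a; v2 <- d - b
  c1 <- sum(v1 * v2) / max(sqrt(sum(v1^2) * sum(v2^2)), 1e-300)
  acos(min(max(c1, -1), 1)) * 180 / pi
}

# Sharp-corner polish: total-least-squares lines through the contour points
# 2..8 samples away on each side of the corner, intersected.
refine_tip_lines <- function(rs, i0) {
  n <- nrow(rs)
  side <- function(dir) {
    idx <- ((i0 - 1 + dir * (2:8)) %% n) + 1
    p <- rs[idx, , drop = FALSE]
    ctr <- colMeans(p)
    v <- svd(sweep(p, 2, ctr))$v[, 1]
    list(p0 = ctr, v = v)
  }
  s1 <- side(1); s2 <- side(-1)
  A <- cbind(s1$v, -s2$v)
  if (abs(det(A)) < 1e-6) return(NULL)
  t <- solve(A, s2$p0 - s1$p0)
  tp <- s1$p0 + t[1] * s1$v
  if (sqrt(sum((tp - rs[i0, ])^2)) > 3) return(NULL)
  tp
}





# Joint twin-ellipse fit: the two lens arcs are segments of the two rim-
# circle images, which are to high accuracy one ellipse and a translated,
# slightly rescaled copy (the rims are parallel equal circles at slightly
# different depths). Fitting all 8 parameters (ellipse 5 + shift 2 + scale 1)
# to both arcs jointly conditions the problem far better than two separate
# single-arc fits, and the tips follow as the conic intersection.
fit_twin_ellipses <- function(p1, p2, k2, max_iter = 30L) {
  c1 <- circle_fit_kasa(p1); c2 <- circle_fit_kasa(p2)
  if (is.null(c1) || is.null(c2)) return(NULL)
  shift0 <- c2$center_px - c1$center_px
  smag0 <- sqrt(sum(shift0^2))
  a0 <- (c1$radius_px + c2$radius_px) / 2
  th0 <- asin(min(max(smag0 / (2 * k2 * a0), 0.01), 0.95))
  psi0 <- atan2(shift0[2], shift0[1])          # minor-axis (tilt) direction
  ctr0 <- (c1$center_px + c2$center_px) / 2 - shift0 / 2
  # parameters: center (of rim 1), semi-major a, obliquity theta, tilt
  # direction psi; the rims' relative magnification is within ~1% of unity
  # and is fixed there (a free ratio drifts and drags the size estimate)
  th <- c(ctr0, a0, th0, psi0)
  geom <- function(th) {
    a <- th[3]; theta <- th[4]; psi <- th[5]
    b <- a * cos(theta)
    sdir <- c(cos(psi), sin(psi))
    shift <- 2 * k2 * a * sin(theta) * sdir
    phi <- psi + pi / 2                         # major axis perp to tilt
    list(a = a, b = b, phi = phi, shift = shift)
  }
  resid <- function(th) {
    g <- geom(th)
    d1 <- ellipse_point_dist(p1, th[1:2], c(g$a, g$b), g$phi)
    d2 <- ellipse_point_dist(p2, th[1:2] + g$shift, c(g$a, g$b), g$phi)
    c(d1, d2)
  }
  r <- resid(th)
  cost <- sum(r^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), 5)
    eps <- c(1e-5, 1e-5, 1e-5, 1e-7, 1e-7)
    for (j in 1:5) {
      tj <- th; tj[j] <- tj[j] + eps[j]
      J[, j] <- (resid(tj) - r) / eps[j]
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    ok <- FALSE
    for (try in 1:8) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        th_new <- th + as.numeric(step)
        if (th_new[3] > 1 && th_new[4] > 0.001 && th_new[4] < 1.4) {
          r_new <- resid(th_new)
          if (sum(r_new^2) < cost) {
            th <- th_new; r <- r_new; cost <- sum(r^2)
            lambda <- max(lambda / 3, 1e-10)
            ok <- TRUE
            break
          }
        }
      }
      lambda <- lambda * 8
    }
    if (!ok || max(abs(g)) < 1e-10) break
  }
  gg <- geom(th)
  e1 <- tryCatch(ellipse_conic(th[1:2], c(gg$a, gg$b), gg$phi),
                 error = function(e) NULL)
  e2 <- tryCatch(ellipse_conic(th[1:2] + gg$shift, c(gg$a, gg$b), gg$phi),
                 error = function(e) NULL)
  if (is.null(e1) || is.null(e2)) return(NULL)
  list(e1 = e1, e2 = e2, rms = sqrt(mean(r^2)), obliquity_rad = th[4])
}

# First-order distance of points to an ellipse (algebraic value over gradient).
ellipse_point_dist <- function(p, ctr, ab, phi) {
  ct <- cos(phi); st <- sin(phi)
  dx <- p[, 1] - ctr[1]; dy <- p[, 2] - ctr[2]
  x <- dx * ct + dy * st
  y <- -dx * st + dy * ct
  q <- (x / ab[1])^2 + (y / ab[2])^2 - 1
  gx <- 2 * x / ab[1]^2; gy <- 2 * y / ab[2]^2
  q / pmax(sqrt(gx^2 + gy^2), 1e-300)
}

# Tip refinement by local parabola extrapolation: the traced contour rounds
# the sharp lens corners over the blur radius, so each arc is extrapolated
# into the corner from its clean interior points (a window 3-11 px from the
# rough tip, in the local frame whose x-axis is the tip-to-tip chord) and
# the two extrapolated branches are intersected.

# Kasa circle fit to the interior of an arc (blurred corner zones trimmed).

# Intersection points of two circles, or NULL.

# Parabolic refinement of the apex along the contour.
refine_apex <- function(ap, ia, t1, t2) {
  n <- nrow(ap)
  if (ia <= 1 || ia >= n) return(as.numeric(ap[ia, ]))
  d0 <- chord_distance(ap[(ia - 1):(ia + 1), , drop = FALSE], t1, t2)
  denom <- d0[1] - 2 * d0[2] + d0[3]
  if (abs(denom) < 1e-12) return(as.numeric(ap[ia, ]))
  delta <- 0.5 * (d0[1] - d0[3]) / denom
  delta <- max(min(delta, 1), -1)
  if (delta >= 0) {
    as.numeric(ap[ia, ] + delta * (ap[ia + 1, ] - ap[ia, ]))
  } else {
    as.numeric(ap[ia, ] - delta * (ap[ia - 1, ] - ap[ia, ]))
  }
}
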