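# Conic sections on the detector plane.
#
# A conic is stored by its six homogeneous coefficients (A, B, C, D, E, F) of
# A u^2 + B u v + C v^2 + D u + E v + F = 0, scaled to a unit coefficient
# vector with A + C > 0 so that the interior of an ellipse evaluates negative.
# When the conic is a real ellipse the derived center / semi-axes / orientation
# form is attached.

#' Construct a conic from its six homogeneous coefficients
#'
#' @param coef numeric length 6: (A, B, C, D, E, F) of
#'   `A u^2 + B u v + C v^2 + D u + E v + F = 0` in pixel coordinates.
#' @return An object of class `conic2d` with elements `coef` (unit-normalized)
#'   and, when the conic is a real ellipse, `center_px`, `semi_axes_px`
#'   (a >= b) and `orientation_rad` (major-axis angle in `[0, pi)`).
#' @export
conic2d <- function(coef) {
  stopifnot(length(coef) == 6L, all(is.finite(coef)))
  nrm <- sqrt(sum(coef^2))
  if (nrm == 0) stop("zero conic")
  coef <- coef / nrm
  s <- coef[1] + coef[3]
  if (s < 0 || (s == 0 && coef[which(coef != 0)[1]] < 0)) coef <- -coef
  obj <- structure(list(coef = coef), class = "conic2d")
  ell <- conic_ellipse_form(coef)
  if (!is.null(ell)) obj[names(ell)] <- ell
  obj
}

#' @export
print.conic2d <- function(x, ...) {
  if (is.null(x$center_px)) {
    cat("<conic2d> (not an ellipse)\n")
  } else {
    cat(sprintf(
      "<conic2d> ellipse center (%.2f, %.2f) px, semi-axes (%.2f, %.2f) px, angle %.1f deg\n",
      x$center_px[1], x$center_px[2], x$semi_axes_px[1], x$semi_axes_px[2],
      x$orientation_rad * 180 / pi
    ))
  }
  invisible(x)
}

conic_matrix <- function(conic) {
  k <- if (inherits(conic, "conic2d")) conic$coef else conic
  matrix(c(k[1], k[2] / 2, k[4] / 2,
           k[2] / 2, k[3], k[5] / 2,
           k[4] / 2, k[5] / 2, k[6]), 3, 3, byrow = TRUE)
}

conic_from_matrix <- function(M) {
  M <- (M + t(M)) / 2
  conic2d(c(M[1, 1], 2 * M[1, 2], M[2, 2], 2 * M[1, 3], 2 * M[2, 3], M[3, 3]))
}

# Ellipse form (center, semi-axes a >= b, major-axis angle), or NULL when the
# conic is not a real ellipse.
conic_ellipse_form <- function(coef) {
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  M2 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  d2 <- det(M2)
  if (d2 <= 0) return(NULL)
  b <- c(coef[4] / 2, coef[5] / 2)
  ctr <- as.numeric(solve(M2, -b))
  f0 <- coef[6] + sum(b * ctr)          # value at the center
  if (f0 >= 0) return(NULL)             # empty or point ellipse
  e <- eigen(M2, symmetric = TRUE)      # eigenvalues decreasing, both > 0
  a_len <- sqrt(-f0 / e$values[2])      # smaller eigenvalue -> major axis
  b_len <- sqrt(-f0 / e$values[1])
  v <- e$vectors[, 2]
  ang <- atan2(v[2], v[1]) %% pi
  list(center_px = ctr, semi_axes_px = c(a_len, b_len), orientation_rad = ang)
}

#' Construct the conic of an ellipse given center, semi-axes and orientation
#'
#' @param center_px length-2 ellipse center in pixels.
#' @param semi_axes_px length-2 semi-axes `(a, b)` in pixels, `a >= b > 0`.
#' @param orientation_rad major-axis angle in radians.
#' @return A [conic2d()].
#' @export
ellipse_conic <- function(center_px, semi_axes_px, orientation_rad = 0) {
  a <- semi_axes_px[1]; b <- semi_axes_px[2]
  stopifnot(a > 0, b > 0)
  ct <- cos(orientation_rad); st <- sin(orientation_rad)
  Rm <- matrix(c(ct, -st, st, ct), 2, 2, byrow = TRUE)
  M2 <- t(Rm) %*% diag(c(1 / a^2, 1 / b^2)) %*% Rm
  bb <- as.numeric(-M2 %*% center_px)
  f <- as.numeric(center_px %*% M2 %*% center_px) - 1
  conic2d(c(M2[1, 1], 2 * M2[1, 2], M2[2, 2], 2 * bb[1], 2 * bb[2], f))
}

#' Evaluate a conic's quadratic form at points
#'
#' Interior points of an ellipse evaluate negative under the package's sign
#' convention.
#'
#' @param conic a [conic2d()].
#' @param pts length-2 point or n x 2 matrix of pixel points.
#' @return numeric vector of conic values.
#' @export
conic_eval <- function(conic, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, nrow = 1)
  k <- conic$coef
  k[1] * pts[, 1]^2 + k[2] * pts[, 1] * pts[, 2] + k[3] * pts[, 2]^2 +
    k[4] * pts[, 1] + k[5] * pts[, 2] + k[6]
}

#' Sample points on an ellipse conic
#'
#' @param conic a [conic2d()] that is a real ellipse.
#' @param t parameter angles in radians (eccentric anomaly).
#' @return n x 2 matrix of pixel points.
#' @export
ellipse_points <- function(conic, t) {
  if (is.null(conic$center_px)) stop("conic is not a real ellipse")
  a <- conic$semi_axes_px[1]; b <- conic$semi_axes_px[2]
  th <- conic$orientation_rad
  x <- a * cos(t); y <- b * sin(t)
  cbind(conic$center_px[1] + x * cos(th) - y * sin(th),
        conic$center_px[2] + x * sin(th) + y * cos(th))
}

# Eccentric-anomaly parameter of points (n x 2) relative to an ellipse conic.
ellipse_param_of <- function(conic, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, nrow = 1)
  th <- conic$orientation_rad
  dx <- pts[, 1] - conic$center_px[1]
  dy <- pts[, 2] - conic$center_px[2]
  x <- dx * cos(th) + dy * sin(th)
  y <- -dx * sin(th) + dy * cos(th)
  atan2(y / conic$semi_axes_px[2], x / conic$semi_axes_px[1])
}

#' Fit a conic to 2D points by algebraic least squares
#'
#' Direct least-squares fit of the unit-norm coefficient vector minimizing the
#' algebraic residual, computed on Hartley-normalized coordinates (centroid
#' shift + isotropic scaling) for numerical stability. The fit is invariant to
#' point ordering and equivariant under uniform scaling of the frame.
#'
#' @param points n x 2 matrix of pixel points, n >= 5.
#' @return A [conic2d()].
#' @export
fit_conic <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 5L) stop("fit_conic needs at least 5 points")
  ctr <- colMeans(points)
  xc <- points[, 1] - ctr[1]; yc <- points[, 2] - ctr[2]
  sc <- sqrt(mean(xc^2 + yc^2) / 2)
  if (sc < 1e-12) stop("degenerate fit: points are coincident")
  # collinearity check on the centered coordinates
  sv2 <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv2[2] < 1e-9 * max(sv2[1], 1)) {
    stop("degenerate fit: points are collinear")
  }
  x <- xc / sc; y <- yc / sc
  Dm <- cbind(x^2, x * y, y^2, x, y, 1)
  k <- svd(Dm, nu = 0, nv = 6)$v[, 6]
  # un-normalize: substitute x = (u - cu)/s, y = (v - cv)/s
  s <- sc; cu <- ctr[1]; cv <- ctr[2]
  A <- k[1] / s^2
  B <- k[2] / s^2
  C <- k[3] / s^2
  D <- -2 * k[1] * cu / s^2 - k[2] * cv / s^2 + k[4] / s
  E <- -k[2] * cu / s^2 - 2 * k[3] * cv / s^2 + k[5] / s
  F <- k[1] * cu^2 / s^2 + k[2] * cu * cv / s^2 + k[3] * cv^2 / s^2 -
    k[4] * cu / s - k[5] * cv / s + k[6]
  conic2d(c(A, B, C, D, E, F))
}

adjugate3 <- function(M) {
  # transpose of the cofactor matrix; for symmetric M the adjugate is symmetric
  out <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    out[j, i] <- (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
  }
  out
}

# Intersect a homogeneous line l with conic matrix M; 0, 1 or 2 real points.
line_conic_points <- function(l, M) {
  n2 <- l[1]^2 + l[2]^2
  if (n2 < 1e-14 * sum(l^2)) return(matrix(numeric(0), 0, 2))  # line at infinity
  p0 <- c(-l[3] * l[1] / n2, -l[3] * l[2] / n2, 1)
  h <- c(l[2], -l[1], 0)
  alpha <- as.numeric(h %*% M %*% h)
  beta <- as.numeric(2 * h %*% M %*% p0)
  gamma <- as.numeric(p0 %*% M %*% p0)
  if (abs(alpha) < 1e-14 * (abs(beta) + abs(gamma) + 1e-300)) {
    if (abs(beta) < 1e-300) return(matrix(numeric(0), 0, 2))
    svals <- -gamma / beta
  } else {
    disc <- beta^2 - 4 * alpha * gamma
    if (disc < 0) return(matrix(numeric(0), 0, 2))
    sq <- sqrt(disc)
    svals <- c((-beta + sq) / (2 * alpha), (-beta - sq) / (2 * alpha))
  }
  cbind(p0[1] + svals * h[1], p0[2] + svals * h[2])
}

# Split a degenerate (rank <= 2) conic matrix into one or two homogeneous
# lines. Returns a list of lines or NULL when the lines are complex.
split_degenerate_conic <- function(D) {
  Badj <- adjugate3(D)
  dg <- diag(Badj)
  i <- which.max(abs(dg))
  scale_ref <- max(abs(D))
  if (abs(dg[i]) < 1e-10 * scale_ref^2) {
    # rank 1: D ~ l l^T, read the line off the largest row
    r <- which.max(rowSums(abs(D)))
    l <- D[r, ]
    if (D[r, r] < 0) l <- -l
    l <- sign_sqrt_row(D, r)
    return(list(l))
  }
  if (dg[i] > 0) return(NULL)  # complex line pair
  q <- Badj[, i] / sqrt(-dg[i])
  for (sgn in c(1, -1)) {
    P <- D + sgn * skew3(q)
    idx <- which(abs(P) == max(abs(P)), arr.ind = TRUE)[1, ]
    l1 <- P[idx[1], ]
    l2 <- P[, idx[2]]
    # accept the sign for which P is (near) rank 1
    s <- svd(P, nu = 0, nv = 0)$d
    if (s[2] < 1e-6 * s[1]) return(list(l1, l2))
  }
  # fall back: pick the sign with smaller second singular value
  P1 <- D + skew3(q); P2 <- D - skew3(q)
  s1 <- svd(P1, nu = 0, nv = 0)$d; s2 <- svd(P2, nu = 0, nv = 0)$d
  P <- if (s1[2] / s1[1] < s2[2] / s2[1]) P1 else P2
  idx <- which(abs(P) == max(abs(P)), arr.ind = TRUE)[1, ]
  list(P[idx[1], ], P[, idx[2]])
}

sign_sqrt_row <- function(D, r) {
  d <- diag(D)
  l <- sqrt(pmax(d, 0))
  l <- l * ifelse(D[r, ] < 0, -1, 1)
  if (l[r] == 0) l <- D[r, ]
  l
}

#' Intersect two conics
#'
#' Real intersection points of two real ellipses, computed by the degenerate
#' member of the conic pencil (classical method) and polished by Newton
#' iteration on both quadratic forms. Numerically coincident conics are
#' flagged rather than intersected.
#'
#' @param c1,c2 [conic2d()] objects (real ellipses).
#' @param tol residual tolerance in the unit-normalized quadratic forms.
#' @return list with `points` (n x 2 matrix, n in 0..4) and `coincident` flag.
#' @export
intersect_conics <- function(c1, c2, tol = 1e-6) {
  if (is.null(c1$center_px) || is.null(c2$center_px)) {
    stop("intersect_conics expects two real ellipses")
  }
  dd <- min(sqrt(sum((c1$coef - c2$coef)^2)), sqrt(sum((c1$coef + c2$coef)^2)))
  if (dd < 1e-9) {
    return(list(points = matrix(numeric(0), 0, 2), coincident = TRUE))
  }
  # normalize coordinates: common shift and scale keeps the pencil stable
  ctr <- (c1$center_px + c2$center_px) / 2
  sc <- mean(c(c1$semi_axes_px, c2$semi_axes_px))
  Tm <- matrix(c(sc, 0, ctr[1], 0, sc, ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
  A <- t(Tm) %*% conic_matrix(c1) %*% Tm
  B <- t(Tm) %*% conic_matrix(c2) %*% Tm
  A <- A / max(abs(A)); B <- B / max(abs(B))

  # cubic det(A + lambda B) by interpolation at 4 nodes
  f <- vapply(c(0, 1, -1, 2), function(l) det(A + l * B), numeric(1))
  c0 <- f[1]
  # solve for c1..c3 from f(1), f(-1), f(2)
  rhs <- c(f[2] - c0, f[3] - c0, f[4] - c0)
  Vm <- matrix(c(1, 1, 1, -1, 1, -1, 2, 4, 8), 3, 3, byrow = TRUE)
  cc <- solve(Vm, rhs)
  roots <- tryCatch(polyroot(c(c0, cc)), error = function(e) complex(0))
  mag <- max(abs(roots), 1)
  real_roots <- Re(roots[abs(Im(roots)) < 1e-7 * mag])

  pts <- matrix(numeric(0), 0, 2)
  for (lam in real_roots) {
    lines <- split_degenerate_conic(A + lam * B)
    if (is.null(lines)) next
    for (l in lines) {
      p <- line_conic_points(l, A)
      if (nrow(p)) pts <- rbind(pts, p)
    }
    if (nrow(pts)) break
  }
  if (!nrow(pts)) return(list(points = matrix(numeric(0), 0, 2), coincident = FALSE))

  # back to pixel coordinates
  pts <- cbind(pts[, 1] * sc + ctr[1], pts[, 2] * sc + ctr[2])
  pts <- newton_polish_conics(pts, c1, c2)
  res <- pmax(abs(conic_eval(c1, pts)), abs(conic_eval(c2, pts)))
  pts <- pts[res < tol, , drop = FALSE]
  pts <- dedupe_points(pts, tol = 1e-4 * max(sc, 1))
  list(points = pts, coincident = FALSE)
}

newton_polish_conics <- function(pts, c1, c2, iters = 12) {
  k1 <- c1$coef; k2 <- c2$coef
  for (it in seq_len(iters)) {
    f1 <- conic_eval(c1, pts); f2 <- conic_eval(c2, pts)
    g1u <- 2 * k1[1] * pts[, 1] + k1[2] * pts[, 2] + k1[4]
    g1v <- k1[2] * pts[, 1] + 2 * k1[3] * pts[, 2] + k1[5]
    g2u <- 2 * k2[1] * pts[, 1] + k2[2] * pts[, 2] + k2[4]
    g2v <- k2[2] * pts[, 1] + 2 * k2[3] * pts[, 2] + k2[5]
    det_j <- g1u * g2v - g1v * g2u
    bad <- abs(det_j) < 1e-300
    det_j[bad] <- 1
    du <- (f1 * g2v - f2 * g1v) / det_j
    dv <- (g1u * f2 - g2u * f1) / det_j
    du[bad] <- 0; dv[bad] <- 0
    pts <- cbind(pts[, 1] - du, pts[, 2] - dv)
    if (max(abs(c(du, dv))) < 1e-12) break
  }
  pts
}

dedupe_points <- function(pts, tol = 1e-4) {
  if (nrow(pts) <= 1) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in 2:nrow(pts)) {
    for (j in 1:(i - 1)) {
      if (keep[j] && sum((pts[i, ] - pts[j, ])^2) < tol^2) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pts[keep, , drop = FALSE]
}
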