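# 3D circles under the cone-beam map: exact projection and the classical
# single-view circle pose problem (with its two-fold mirror ambiguity).

#' A circle in 3D camera-frame coordinates
#'
#' Used for the rim circles of the interlocking-hole cylinders and for the
#' radio-opaque targeting rings of the drill jig.
#'
#' @param center_mm length-3 circle center in mm (camera frame).
#' @param normal length-3 plane normal; normalized internally.
#' @param radius_mm circle radius in mm (>= 0; 0 only as a degenerate point).
#' @return An object of class `circle3d`.
#' @export
circle3d <- function(center_mm, normal, radius_mm) {
  stopifnot(length(center_mm) == 3L, length(normal) == 3L, radius_mm >= 0)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("normal must be a nonzero vector")
  structure(
    list(center_mm = as.numeric(center_mm), normal = as.numeric(normal) / n,
         radius_mm = radius_mm),
    class = "circle3d"
  )
}

# Sample n points on a circle3d (n x 3 matrix, camera frame).
circle_points3d <- function(circle, n = 64, t = NULL) {
  if (is.null(t)) t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  b1 <- orthonormal_to(circle$normal)
  b2 <- unit3(crossprod3(circle$normal, b1))
  r <- circle$radius_mm
  sweep(r * (cos(t) %o% b1 + sin(t) %o% b2), 2, circle$center_mm, "+")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Direction-space cone matrix K of the rays through a circle: a ray d (from
# the source at the origin) meets the circle's supporting plane on the circle
# iff d' K d = 0, with K = a^2 I - a (c n' + n c') + (|c|^2 - r^2) n n',
# a = n . c. Exact for any cone-beam view.
circle_cone_matrix <- function(circle) {
  n <- circle$normal; c3 <- circle$center_mm; r <- circle$radius_mm
  a <- sum(n * c3)
  a^2 * diag(3) - a * (c3 %o% n + n %o% c3) + (sum(c3^2) - r^2) * (n %o% n)
}

#' Project a 3D circle to its exact conic image
#'
#' Computes the cone of rays through the source and the circle and intersects
#' it with the detector, giving the exact conic image in pixel coordinates.
#' For every admissible input (whole circle at positive depth, not grazing the
#' source plane) the image is an ellipse; a zero-radius circle degenerates to
#' the projected center point.
#'
#' @param camera a [camera_model()].
#' @param circle a [circle3d()] wholly at positive depth.
#' @return A [conic2d()]; for `radius_mm = 0` a list with `degenerate_point`.
#' @export
project_circle <- function(camera, circle) {
  z_half_range <- circle$radius_mm * sqrt(max(0, 1 - circle$normal[3]^2))
  if (circle$center_mm[3] - z_half_range <= 0) {
    stop("degenerate projection: circle crosses the z = 0 plane")
  }
  if (circle$radius_mm == 0) {
    return(structure(
      list(degenerate_point = project_point(camera, circle$center_mm)),
      class = c("degenerate_conic", "conic2d")
    ))
  }
  K <- circle_cone_matrix(circle)
  Tm <- camera_pixel_to_dir_matrix(camera)
  conic_from_matrix(t(Tm) %*% K %*% Tm)
}

#' Closed-form circle pose candidates from one conic image
#'
#' Recovers the two mirror-ambiguous 3D poses of a circle of known radius from
#' its elliptical image: the cone of rays through the conic is eigen-decomposed
#' and cut by the two plane orientations that yield circular cross sections;
#' the known radius fixes the depth. This is the classical single-view circle
#' pose problem; the ambiguity collapses when the circle is viewed head on.
#'
#' @param camera a [camera_model()].
#' @param conic [conic2d()] image of the circle (a real ellipse).
#' @param radius_mm known circle radius in mm.
#' @return list of one or two [circle3d()] candidates (normals oriented with
#'   positive z-component toward the detector; centers at positive depth).
#' @export
circle_pose_candidates <- function(camera, conic, radius_mm) {
  if (is.null(conic$center_px)) stop("conic image must be a real ellipse")
  Tm <- camera_pixel_to_dir_matrix(camera)
  Ti <- solve(Tm)
  K <- t(Ti) %*% conic_matrix(conic) %*% Ti
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  # signature must be (+, +, -): flip sign so two eigenvalues are positive
  if (sum(e$values > 0) == 1) {
    e$values <- -rev(e$values)
    e$vectors <- e$vectors[, 3:1]
  }
  lam <- e$values            # lam1 >= lam2 > 0 > lam3
  if (!(lam[1] >= lam[2] && lam[2] > 0 && lam[3] < 0)) {
    stop("conic does not define a real circle cone")
  }
  g <- sqrt((lam[1] - lam[2]) / (lam[1] - lam[3]))
  h <- sqrt((lam[2] - lam[3]) / (lam[1] - lam[3]))
  normals <- list(g * e$vectors[, 1] + h * e$vectors[, 3],
                  g * e$vectors[, 1] - h * e$vectors[, 3])
  if (g < 1e-9) normals <- normals[1]  # head-on view: ambiguity collapses
  out <- lapply(normals, function(n) {
    circle_on_cone(K, unit3(n), radius_mm)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) stop("no valid circle pose for this conic")
  out
}

# Cut the cone d'Kd = 0 with the plane n.x = alpha and scale alpha so the
# cross section is a circle of the requested radius at positive depth.
circle_on_cone <- function(K, n, radius_mm) {
  b1 <- orthonormal_to(n)
  b2 <- unit3(crossprod3(n, b1))
  M <- rbind(
    c(b1 %*% K %*% b1, b1 %*% K %*% b2),
    c(b2 %*% K %*% b1, b2 %*% K %*% b2)
  )
  v <- c(b1 %*% K %*% n, b2 %*% K %*% n)
  knn <- as.numeric(n %*% K %*% n)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] + ev[2] < 0) {                           # cone matrix sign is arbitrary
    M <- -M; v <- -v; knn <- -knn; ev <- -rev(ev)
  }
  if (ev[2] <= 0) return(NULL)                       # plane does not cut a closed curve
  if (abs(ev[1] - ev[2]) > 1e-4 * abs(ev[1])) return(NULL)  # not circular
  mu <- (ev[1] + ev[2]) / 2
  # section at n.x = alpha: mu |s|^2 + 2 alpha v.s + alpha^2 knn = 0
  ctr2 <- -v / mu                                    # for alpha = 1
  r2 <- sum(ctr2^2) - knn / mu                       # radius^2 at alpha = 1
  if (r2 <= 0) return(NULL)
  alpha <- radius_mm / sqrt(r2)
  center <- alpha * (n + ctr2[1] * b1 + ctr2[2] * b2)
  if (center[3] < 0) {
    alpha <- -alpha
    center <- -center
  }
  nn <- if (n[3] < 0) -n else n
  circle3d(center, nn, radius_mm)
}
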