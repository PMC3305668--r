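# Ray-cast synthetic radiograph generator (digitally reconstructed
# radiograph of the nail's distal segment) and the reproducible fixture
# catalogue used throughout the test suite.
#
# The nail is a CSG solid: a finite cylinder of radius R minus the two hole
# cylinders of radius r_h. Per-pixel path lengths through the metal follow
# Beer-Lambert attenuation, exp(-mu * path). This renderer is the exact
# oracle bounding the planar-rim approximation of the analytic forward model.

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Ray/cylinder intersection for rays t * d from the origin.
# d: n x 3 directions; axis point a, unit axis w, radius rho.
# Returns cbind(t0, t1) with t0 >= t1 meaning empty.
ray_cylinder_interval <- function(d, a, w, rho) {
  dw <- d %*% w
  aw <- sum(a * w)
  dpx <- d[, 1] - dw * w[1]
  dpy <- d[, 2] - dw * w[2]
  dpz <- d[, 3] - dw * w[3]
  apx <- a[1] - aw * w[1]
  apy <- a[2] - aw * w[2]
  apz <- a[3] - aw * w[3]
  A <- dpx^2 + dpy^2 + dpz^2
  B <- -2 * (dpx * apx + dpy * apy + dpz * apz)
  C <- apx^2 + apy^2 + apz^2 - rho^2
  disc <- B^2 - 4 * A * C
  bad <- disc <= 0 | A <= 1e-300
  sq <- sqrt(pmax(disc, 0))
  inv <- 1 / (2 * pmax(A, 1e-300))
  t0 <- (-B - sq) * inv
  t1 <- (-B + sq) * inv
  t0[bad] <- 1
  t1[bad] <- 0
  cbind(t0, t1)
}

# Clip interval (t0, t1) to the slab |(t d - a) . w| <= half_len.
clip_to_slab <- function(iv, d, a, w, half_len) {
  dw <- as.numeric(d %*% w)
  aw <- sum(a * w)
  lo <- (aw - half_len) / dw
  hi <- (aw + half_len) / dw
  s0 <- pmin(lo, hi)
  s1 <- pmax(lo, hi)
  par <- abs(dw) < 1e-12
  if (any(par)) {
    # ray parallel to the slab: inside for all t or none
    inside <- abs(-aw) <= half_len  # (t d - a) . w = -a . w for dw ~ 0
    s0[par] <- if (inside) -Inf else 1
    s1[par] <- if (inside) Inf else 0
  }
  cbind(pmax(iv[, 1], s0), pmin(iv[, 2], s1))
}

#' Render a synthetic radiograph of the nail
#'
#' Casts one ray per pixel through the nail solid (outer cylinder minus open
#' hole channels), applies Beer-Lambert attenuation with coefficient `mu_mm`,
#' adds Gaussian intensity noise and optionally min-max normalizes the image
#' (emulating a C-arm's automatic intensity correction). Deterministic given
#' `seed`.
#'
#' @param camera a [camera_model()].
#' @param nail a [nail_spec()].
#' @param pose a [nail_pose()].
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed integer RNG seed for the noise.
#' @param screw_in_hole integer vector of hole indices occupied by a screw
#'   (those channels are not subtracted, i.e. appear radio-opaque).
#' @param mu_mm linear attenuation coefficient of the implant metal, per mm.
#' @param normalize min-max normalize intensities to `[0, 1]` after noise.
#' @param background_gradient amplitude of an optional smooth horizontal
#'   background gradient (detector robustness testing aid).
#' @return A `synthetic_image`: list with `pixels` (h x w matrix in `[0, 1]`),
#'   `ground_truth` (the pose), `ground_truth_contours` (per-hole analytic
#'   [lens_contour_object()] or `NULL` for occupied/empty holes), `camera`,
#'   `nail`, `rng_seed`.
#' @export
render_radiograph <- function(camera, nail, pose, noise_sigma = 0, seed = 1L,
                              screw_in_hole = integer(0), mu_mm = 20,
                              normalize = TRUE, background_gradient = 0) {
  w_px <- camera$image_size_px[1]
  h_px <- camera$image_size_px[2]
  uv <- cbind(rep(0:(w_px - 1), each = h_px), rep(0:(h_px - 1), w_px))
  d <- pixel_to_ray(camera, uv)
  dn <- sqrt(rowSums(d^2))

  axis_w <- as.numeric(pose$rotation %*% c(0, 0, 1))
  st <- vapply(nail$holes, function(h) h$axial_station_mm, numeric(1))
  mid <- pose_apply(pose, c(0, 0, mean(st)))
  iv <- ray_cylinder_interval(d, mid, axis_w, nail$outer_radius_mm)
  iv <- clip_to_slab(iv, d, mid, axis_w, nail$length_mm / 2)
  len_outer <- pmax(iv[, 2] - iv[, 1], 0)
  path <- len_outer
  for (k in 1:2) {
    if (k %in% screw_in_hole) next
    hc <- hole_axis_camera(nail, pose, k)
    hv <- ray_cylinder_interval(d, hc$center, hc$axis, nail$hole_radius_mm)
    h0 <- pmax(hv[, 1], iv[, 1])
    h1 <- pmin(hv[, 2], iv[, 2])
    path <- path - pmax(h1 - h0, 0)
  }
  path <- pmax(path, 0) * dn  # t-parameter spans scaled to mm along the ray
  img <- exp(-mu_mm * path)
  if (background_gradient != 0) {
    img <- img * (1 - background_gradient * uv[, 1] / max(w_px - 1, 1))
  }
  img <- matrix(img, nrow = h_px, ncol = w_px)  # column u major -> [v, u]
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sigma),
                                        h_px, w_px))
  }
  img <- if (normalize) {
    rng <- range(img)
    if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  } else {
    pmin(pmax(img, 0), 1)
  }
  gt_contours <- lapply(1:2, function(k) {
    if (k %in% screw_in_hole) return(NULL)
    tryCatch(lens_contour(camera, nail, pose, k),
             nailguide_empty_lens = function(e) NULL)
  })
  structure(
    list(pixels = img, ground_truth = pose, ground_truth_contours = gt_contours,
         camera = camera, nail = nail, rng_seed = seed,
         screw_in_hole = screw_in_hole, mu_mm = mu_mm,
         noise_sigma = noise_sigma),
    class = "synthetic_image"
  )
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image> %dx%d px, noise sd %.3f, seed %d\n",
              ncol(x$pixels), nrow(x$pixels), x$noise_sigma, x$rng_seed))
  invisible(x)
}

# Default compact fixture camera: same pitch class as a C-arm intensifier but
# a reduced field of view so the test suite renders quickly.
fixture_camera <- function(size_px = 448L, pitch_mm = 0.2) {
  camera_model(sdd_mm = 1000, pixel_pitch_mm = pitch_mm,
               principal_point_px = c(size_px / 2, size_px / 2),
               image_size_px = c(size_px, size_px))
}

fixture_nail <- function(layout = c("parallel", "orthogonal")) {
  layout <- match.arg(layout)
  if (layout == "parallel") {
    nail_spec(holes = list(hole_spec(0, c(1, 0, 0), "ML"),
                           hole_spec(12, c(1, 0, 0), "ML")))
  } else {
    nail_spec(holes = list(hole_spec(0, c(1, 0, 0), "ML"),
                           hole_spec(12, c(0, 1, 0), "AP")))
  }
}

# Obliquity bands of the fixture catalogue (degrees). The channel geometry
# (hole radius 2 mm, rim offset sqrt(21) mm) admits through-rays only below
# atan(r_h / h_off) ~ 23.6 deg, so the usable oblique band tops out at 20 deg.
scenario_bands <- list(
  "aligned" = c(0, 0.8),
  "mild-oblique" = c(5, 20),
  "steep-oblique" = c(40, 60),
  "one-screw-inserted" = c(5, 20),
  "shifted-frame-pair" = c(5, 20)
)

#' Sample a random admissible pose of the nail
#'
#' Draws a pose with the targeted hole's obliquity inside `band_deg`, the nail
#' axis roughly transverse to the beam and both holes inside the field of
#' view; resamples until the non-targeted hole also projects a usable lens
#' (except in the steep band, where lenses are deliberately absent).
#'
#' @param camera,nail scene description.
#' @param band_deg numeric length-2 obliquity band in degrees for hole 1.
#' @param seed integer seed.
#' @return A [nail_pose()].
#' @export
sample_pose <- function(camera, nail, band_deg = c(5, 20), seed = 1L) {
  with_seed(seed, {
    for (attempt in 1:100) {
      z <- stats::runif(1, 650, 750)
      xy <- stats::runif(2, -8, 8)
      m <- c(xy, z)
      vhat0 <- unit3(m)
      b1 <- orthonormal_to(vhat0)
      b2 <- unit3(crossprod3(vhat0, b1))
      phi <- stats::runif(1, 0, 2 * pi)
      zc <- cos(phi) * b1 + sin(phi) * b2
      st <- vapply(nail$holes, function(h) h$axial_station_mm, numeric(1))
      beta <- stats::runif(1, band_deg[1], band_deg[2]) * pi / 180
      sgn <- sample(c(-1, 1), 1)
      hole0 <- m - mean(st) * zc
      vhat <- unit3(hole0)
      vperp <- unit3(vhat - sum(vhat * zc) * zc)
      a <- cos(beta) * vperp + sgn * sin(beta) * unit3(crossprod3(zc, vperp))
      # map hole 1's nail-frame axis (ML or AP) onto a and the nail axis onto zc
      a_n <- nail$holes[[1]]$axis_dir_nail_frame
      Rn <- cbind(a_n, crossprod3(c(0, 0, 1), a_n), c(0, 0, 1))
      Rc <- cbind(a, crossprod3(zc, a), zc)
      R <- Rc %*% t(Rn)
      pose <- nail_pose(R, hole0 - as.numeric(R %*% c(0, 0, st[1])))
      if (pose_admissible(camera, nail, pose, band_deg)) return(pose)
    }
    stop("could not sample an admissible pose in 100 attempts")
  })
}

pose_admissible <- function(camera, nail, pose, band_deg) {
  ob <- hole_obliquity_deg(nail, pose, 1)
  if (ob < band_deg[1] - 1e-9 || ob > band_deg[2] + 1e-9) return(FALSE)
  steep <- band_deg[1] >= 25
  margin <- 12
  for (k in 1:2) {
    lc <- tryCatch(lens_contour(camera, nail, pose, k),
                   nailguide_empty_lens = function(e) NULL)
    if (steep) {
      if (k == 1 && !is.null(lc)) return(FALSE)
      next
    }
    if (is.null(lc)) return(FALSE)
    if (nrow(lc$points) < 16) return(FALSE)
    rng_u <- range(lc$points[, 1]); rng_v <- range(lc$points[, 2])
    if (rng_u[1] < margin || rng_v[1] < margin ||
        rng_u[2] > camera$image_size_px[1] - 1 - margin ||
        rng_v[2] > camera$image_size_px[2] - 1 - margin) return(FALSE)
    # require a usable lens thickness (detectable region)
    if (!lc$is_circular) {
      area <- polygon_area(lc$points)
      if (area < 60) return(FALSE)
    }
  }
  TRUE
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Generate a reproducible test fixture
#'
#' Scenario catalogue: `"aligned"` (hole 1 viewed nearly head-on, round
#' projection), `"mild-oblique"` (both lenses in the usable 5-20 degree band),
#' `"steep-oblique"` (beyond grazing: no through-rays, empty lens),
#' `"one-screw-inserted"` (hole 1 occupied by a screw), and
#' `"shifted-frame-pair"` (a noise-free frame plus the same frame translated
#' by a stored integer pixel shift).
#'
#' @param scenario_id one of the catalogue names above.
#' @param seed integer seed; same (scenario, seed) is bit-identical.
#' @param camera,nail optional scene overrides (compact defaults otherwise).
#' @param noise_sigma optional override of the scenario's noise level.
#' @return list with `image` (a `synthetic_image`), `camera`, `nail`,
#'   `scenario`, `band_deg`, and for the shifted pair `image_b` and
#'   `shift_px`.
#' @export
make_fixture <- function(scenario_id, seed = 1L, camera = NULL, nail = NULL,
                         noise_sigma = NULL) {
  if (!scenario_id %in% names(scenario_bands)) {
    stop("unknown scenario '", scenario_id, "'; known: ",
         paste(names(scenario_bands), collapse = ", "))
  }
  if (is.null(camera)) camera <- fixture_camera()
  if (is.null(nail)) nail <- fixture_nail("parallel")
  band <- scenario_bands[[scenario_id]]
  if (is.null(noise_sigma)) {
    noise_sigma <- if (scenario_id == "shifted-frame-pair") 0 else 0.01
  }
  pose <- sample_pose(camera, nail, band, seed = seed)
  screw <- if (scenario_id == "one-screw-inserted") 1L else integer(0)
  img <- render_radiograph(camera, nail, pose, noise_sigma = noise_sigma,
                           seed = seed + 1000L, screw_in_hole = screw)
  out <- list(image = img, camera = camera, nail = nail,
              scenario = scenario_id, band_deg = band, seed = seed)
  if (scenario_id == "shifted-frame-pair") {
    shift <- with_seed(seed + 2000L, sample(c(-9:-3, 3:9), 2))
    out$shift_px <- shift
    out$image_b <- img
    out$image_b$pixels <- translate_image(img$pixels, shift[1], shift[2])
  }
  out
}

# Integer-pixel translation with edge replication: pixel (u, v) of the output
# takes the value at (u - du, v - dv), i.e. image content moves by (du, dv).
translate_image <- function(img, du, dv) {
  h <- nrow(img); w <- ncol(img)
  src_u <- pmin(pmax((0:(w - 1)) - du, 0), w - 1) + 1L
  src_v <- pmin(pmax((0:(h - 1)) - dv, 0), h - 1) + 1L
  img[src_v, src_u, drop = FALSE]
}
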