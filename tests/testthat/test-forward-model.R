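# nail forward model: rim circles, analytic lens contour, ray-cast renderer
# and the fixture catalogue

test_that("hole rim circles sit at +/- sqrt(R^2 - r_h^2) along the hole axis", {
  nl <- nail_spec()  # R = 5, r_h = 2
  rims <- hole_rim_circles(nl, nail_pose(), 1)
  off <- sqrt(25 - 4)
  expect_equal(rims[[1]]$center_mm, c(off, 0, 0), tolerance = 1e-12)
  expect_equal(rims[[2]]$center_mm, c(-off, 0, 0), tolerance = 1e-12)
  expect_equal(off, 4.583, tolerance = 1e-3)
  expect_equal(rims[[1]]$radius_mm, 2)
  # rigid-motion equivariance under pure translation
  tr <- nail_pose(translation_mm = c(3, -7, 650))
  rims_t <- hole_rim_circles(nl, tr, 1)
  expect_equal(rims_t[[1]]$center_mm, rims[[1]]$center_mm + c(3, -7, 650))
  expect_equal(rims_t[[1]]$normal, rims[[1]]$normal)
})

test_that("planar-rim approximation error is bounded by the exact CSG rim curve", {
  R <- 5; r_h <- 2
  psi <- seq(0, 2 * pi, length.out = 20001)
  # exact rim: intersection of outer cylinder (axis z) and hole cylinder (axis x)
  x <- sqrt(R^2 - r_h^2 * sin(psi)^2)
  dev <- abs(x - sqrt(R^2 - r_h^2))
  expect_lt(max(dev), 0.45)
  expect_equal(max(dev), R - sqrt(R^2 - r_h^2), tolerance = 1e-6)
})

test_that("nail and hole specs validate invariants", {
  expect_error(hole_spec(0, c(0, 0, 1)), "perpendicular")
  expect_error(nail_spec(outer_radius_mm = 2, hole_radius_mm = 2), "smaller")
  expect_error(nail_spec(holes = list(hole_spec(0, c(1, 0, 0)),
                                      hole_spec(0, c(1, 0, 0)))), "distinct")
})

test_that("beam-aligned hole projects as a circle with no tips", {
  cam <- scene_camera(); nl <- scene_nail()
  hc <- c(10, -5, 700)
  v <- unit3(hc)
  zc <- orthonormal_to(v)
  R <- cbind(v, nailguide:::crossprod3(zc, v), zc)
  pose <- nail_pose(R, hc)
  lc <- lens_contour(cam, nl, pose, 1)
  expect_true(lc$is_circular)
  expect_null(lc$tips)
  rr <- sqrt(rowSums(sweep(lc$points, 2, lc$circle_fit$center_px)^2))
  expect_lt(max(rr) / min(rr) - 1, 1e-3)
})

test_that("oblique lens has two tips and lies inside both rim conics", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(3, band = c(18, 22))
  lc <- lens_contour(cam, nl, pose, 1)
  expect_false(lc$is_circular)
  expect_identical(nrow(lc$tips), 2L)
  for (cc in lc$arc_conics) {
    expect_lt(max(conic_eval(cc, lc$points)), 1e-6)
  }
  # tips are contour members and the arcs partition the contour
  expect_equal(lc$points[lc$tip_idx[1], ], lc$tips[1, ], ignore_attr = TRUE)
  expect_equal(sort(unique(c(lc$arcs[[1]], lc$arcs[[2]]))),
               seq_len(nrow(lc$points)))
})

test_that("extreme obliquity yields the empty-lens signal and zero through-rays", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(2, band = c(40, 60))
  expect_error(lens_contour(cam, nl, pose, 1),
               class = "nailguide_empty_lens")
  # ray-cast oracle: no pixel sees an unobstructed channel through hole 1
  img <- render_radiograph(cam, nl, pose, noise_sigma = 0, normalize = FALSE)
  sil <- img$pixels < 0.05
  # within the silhouette nothing is bright (no through-hole rays)
  expect_lt(max(img$pixels[nailguide:::label_components(sil) > 0]), 0.5)
})

test_that("renderer background, noise statistics and determinism behave", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(4)
  img0 <- render_radiograph(cam, nl, pose, noise_sigma = 0, normalize = FALSE)
  expect_equal(max(img0$pixels), 1)           # rays missing the nail
  expect_gte(min(img0$pixels), 0)
  corner <- img0$pixels[1:20, 1:20]
  expect_true(all(corner == 1))               # background exactly 1 pre-noise
  # noise variance on a mid-gray background (gradient keeps it off the clamp)
  imgn <- render_radiograph(cam, nl, pose, noise_sigma = 0.02, seed = 9,
                            normalize = FALSE, background_gradient = 0.5)
  band <- imgn$pixels[, 200:260]
  ref <- render_radiograph(cam, nl, pose, noise_sigma = 0, normalize = FALSE,
                           background_gradient = 0.5)$pixels[, 200:260]
  noise <- (band - ref)[ref > 0.2 & ref < 0.9]
  expect_gt(length(noise), 1e4)
  expect_lt(abs(stats::var(as.vector(noise)) - 0.02^2), 0.1 * 0.02^2)
  # determinism
  imgn2 <- render_radiograph(cam, nl, pose, noise_sigma = 0.02, seed = 9,
                             normalize = FALSE, background_gradient = 0.5)
  expect_identical(imgn$pixels, imgn2$pixels)
})

test_that("noise-free bright-region boundary matches the analytic lens contour", {
  cam <- scene_camera(); nl <- scene_nail()
  for (seed in c(3, 8)) {
    pose <- scene_pose(seed)
    img <- render_radiograph(cam, nl, pose, noise_sigma = 0, normalize = FALSE)
    for (k in 1:2) {
      gt <- img$ground_truth_contours[[k]]
      loops <- nailguide:::iso_contours(img$pixels, 0.5)
      ctr <- colMeans(gt$points)
      best <- NULL
      for (lp in loops) {
        if (lp$closed && nrow(lp$points) > 8 &&
            nailguide:::point_in_polygon(ctr, lp$points)) {
          best <- lp$points
        }
      }
      expect_false(is.null(best))
      expect_lt(hausdorff_px(best, gt$points), 1)
    }
  }
})

test_that("in-plane rotation about the principal ray rotates the projection", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(5)
  ang <- 0.4
  Rz <- axis_angle_to_rotation(c(0, 0, ang))
  pose2 <- nail_pose(Rz %*% pose$rotation, as.numeric(Rz %*% pose$translation_mm))
  lc1 <- lens_contour(cam, nl, pose, 1)
  lc2 <- lens_contour(cam, nl, pose2, 1)
  pp <- cam$principal_point_px
  pitch_rot <- function(p) {
    d <- sweep(p, 2, pp)
    cbind(pp[1] + d[, 1] * cos(ang) - d[, 2] * sin(ang),
          pp[2] + d[, 1] * sin(ang) + d[, 2] * cos(ang))
  }
  rot_pts <- pitch_rot(lc1$points)
  # rotated contour points satisfy the rotated pose's rim conics
  e1 <- lc2$arc_conics[[1]]; e2 <- lc2$arc_conics[[2]]
  expect_lt(max(pmin(abs(conic_eval(e1, rot_pts)), abs(conic_eval(e2, rot_pts)))),
            1e-3)
  expect_lt(max(abs(sort(sqrt(rowSums(sweep(lc1$tips, 2, pp)^2))) -
                    sort(sqrt(rowSums(sweep(lc2$tips, 2, pp)^2))))), 1e-3)
})

test_that("lens area grows monotonically toward the aligned disc area", {
  cam <- scene_camera(); nl <- scene_nail()
  areas <- c()
  for (ob in c(18, 14, 10, 6, 3)) {
    pose <- scene_pose(6, band = c(ob - 0.5, ob + 0.5))
    lc <- lens_contour(cam, nl, pose, 1)
    areas <- c(areas, nailguide:::polygon_area(lc$points))
  }
  expect_true(all(diff(areas) > 0))
  pose0 <- scene_pose(6, band = c(0, 0.8))
  lc0 <- lens_contour(cam, nl, pose0, 1)
  disc <- nailguide:::polygon_area(lc0$points)
  expect_gt(disc, max(areas))
})

test_that("make_fixture is deterministic and respects its bands", {
  f1 <- make_fixture("mild-oblique", seed = 12)
  f2 <- make_fixture("mild-oblique", seed = 12)
  expect_identical(f1$image$pixels, f2$image$pixels)
  ob <- nailguide:::hole_obliquity_deg(f1$nail, f1$image$ground_truth, 1)
  expect_gte(ob, 5); expect_lte(ob, 35)
  fa <- make_fixture("aligned", seed = 3)
  expect_lt(nailguide:::hole_obliquity_deg(fa$nail, fa$image$ground_truth, 1), 2)
  expect_error(make_fixture("nope"), "unknown scenario")
})

test_that("shifted-frame-pair's second frame is the stored translation of the first", {
  fx <- make_fixture("shifted-frame-pair", seed = 5)
  expect_identical(
    fx$image_b$pixels,
    nailguide:::translate_image(fx$image$pixels, fx$shift_px[1], fx$shift_px[2])
  )
  # interior pixels shifted exactly (array-shift oracle)
  du <- fx$shift_px[1]; dv <- fx$shift_px[2]
  h <- nrow(fx$image$pixels); w <- ncol(fx$image$pixels)
  vs <- (max(1, 1 - dv) + 12):(min(h, h - dv) - 12)
  us <- (max(1, 1 - du) + 12):(min(w, w - du) - 12)
  expect_identical(fx$image_b$pixels[vs + dv, us + du],
                   fx$image$pixels[vs, us])
})

test_that("screw-occupied holes render radio-opaque", {
  fx <- make_fixture("one-screw-inserted", seed = 4, noise_sigma = 0)
  expect_null(fx$image$ground_truth_contours[[1]])
  expect_false(is.null(fx$image$ground_truth_contours[[2]]))
  open_img <- render_radiograph(fx$camera, fx$nail, fx$image$ground_truth,
                                noise_sigma = 0)
  # with the screw, the hole-1 lens region is dark instead of bright
  gt1 <- open_img$ground_truth_contours[[1]]
  inside <- round(colMeans(gt1$points)) + 1
  expect_lt(fx$image$pixels[inside[2], inside[1]], 0.3)
  expect_gt(open_img$pixels[inside[2], inside[1]], 0.7)
})
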