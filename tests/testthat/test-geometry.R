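# geometry core: point/circle projection and conic intersection

test_that("project_point follows the cone-beam similar-triangle model", {
  cam <- test_camera()
  expect_equal(unname(project_point(cam, c(0, 0, 500))), c(512, 512))
  # magnification SDD/z = 2, 50 mm offset -> 100 mm -> 200 px at 0.5 mm pitch
  expect_equal(unname(project_point(cam, c(50, 0, 500))), c(712, 512))
  expect_error(project_point(cam, c(0, 0, -10)), "degenerate")
  expect_error(project_point(cam, c(1, 2, 0)), "degenerate")
})

test_that("camera_model validates its invariants", {
  expect_error(camera_model(sdd_mm = -1), "sdd")
  expect_error(camera_model(pixel_pitch_mm = 0), "pitch")
  expect_error(camera_model(principal_point_px = c(5000, 512)), "principal")
})

test_that("project_circle matches the dense point-sampling oracle", {
  cam <- test_camera()
  # frontoparallel circle: image is a centered circle of radius r * mag / pitch
  co <- project_circle(cam, circle3d(c(0, 0, 500), c(0, 0, 1), 10))
  expect_equal(co$center_px, c(512, 512), tolerance = 1e-9)
  expect_equal(co$semi_axes_px, c(40, 40), tolerance = 1e-9)
  # general circles: every sampled 3D point lies on the conic
  for (seed in 1:10) {
    set.seed(seed)
    ci <- circle3d(c(runif(2, -60, 60), runif(1, 300, 800)),
                   unit3(rnorm(3)), runif(1, 2, 30))
    if (ci$center_mm[3] - ci$radius_mm <= 1) next
    co <- project_circle(cam, ci)
    pts <- project_point(cam, circle_points3d(ci, 128))
    expect_lt(max(abs(conic_eval(co, pts))), 1e-9)
    expect_false(is.null(co$center_px))  # always an ellipse
  }
})

test_that("project_circle degenerates and errors as specified", {
  cam <- test_camera()
  d <- project_circle(cam, circle3d(c(10, -20, 400), c(0, 0, 1), 0))
  expect_equal(unname(d$degenerate_point),
               unname(project_point(cam, c(10, -20, 400))))
  expect_error(project_circle(cam, circle3d(c(0, 0, 5), c(1, 0, 0), 10)),
               "degenerate")
})

test_that("tilted circle approaches the cos(theta) axis ratio in the telecentric limit", {
  cam <- test_camera()
  ci <- circle3d(c(0, 0, 1e4), unit3(c(sin(pi / 3), 0, cos(pi / 3))), 10)
  co <- project_circle(cam, ci)
  expect_equal(co$semi_axes_px[2] / co$semi_axes_px[1], cos(pi / 3),
               tolerance = 1e-3)
})

test_that("a source-aligned circle on the principal ray projects to a circle", {
  cam <- test_camera()
  co <- project_circle(cam, circle3d(c(0, 0, 600), c(0, 0, 1), 7))
  expect_lt(abs(co$semi_axes_px[1] / co$semi_axes_px[2] - 1), 1e-9)
})

test_that("intersect_conics solves the classical two-circle case", {
  c1 <- ellipse_conic(c(0, 0), c(1, 1))
  c2 <- ellipse_conic(c(1, 0), c(1, 1))
  ix <- intersect_conics(c1, c2)
  expect_false(ix$coincident)
  pts <- ix$points[order(ix$points[, 2]), ]
  expect_equal(pts, rbind(c(0.5, -sqrt(3) / 2), c(0.5, sqrt(3) / 2)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("intersect_conics flags coincident conics and finds empty sets", {
  c1 <- ellipse_conic(c(3, 4), c(2, 1), 0.3)
  expect_true(intersect_conics(c1, c1)$coincident)
  far <- ellipse_conic(c(30, 4), c(2, 1), 0.1)
  ix <- intersect_conics(c1, far)
  expect_identical(nrow(ix$points), 0L)
  # brute-force grid oracle: no sign change region shared by both interiors
  gx <- seq(-40, 40, by = 0.25)
  grid <- as.matrix(expand.grid(gx, gx))
  both_inside <- conic_eval(c1, grid) < 0 & conic_eval(far, grid) < 0
  expect_false(any(both_inside))
})

test_that("intersect_conics residuals stay below 1e-6 on random crossing pairs", {
  set.seed(42)
  found <- 0
  for (i in 1:40) {
    e1 <- ellipse_conic(runif(2, -5, 5), sort(runif(2, 1, 6), decreasing = TRUE),
                        runif(1, 0, pi))
    e2 <- ellipse_conic(runif(2, -5, 5), sort(runif(2, 1, 6), decreasing = TRUE),
                        runif(1, 0, pi))
    ix <- intersect_conics(e1, e2)
    if (ix$coincident || nrow(ix$points) == 0) next
    found <- found + 1
    expect_lt(max(abs(conic_eval(e1, ix$points))), 1e-6)
    expect_lt(max(abs(conic_eval(e2, ix$points))), 1e-6)
    # every returned point verified against a dense boundary walk of e1
    tt <- seq(0, 2 * pi, length.out = 2000)
    bd <- ellipse_points(e1, tt)
    expect_lt(max(dist_to_polygon(ix$points, bd)), 0.01)
  }
  expect_gte(found, 10)
})

test_that("rotation helpers round-trip", {
  set.seed(7)
  for (i in 1:20) {
    w <- rnorm(3) * runif(1, 0, pi)
    R <- axis_angle_to_rotation(w)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(axis_angle_to_rotation(rotation_to_axis_angle(R)), R,
                 tolerance = 1e-9)
    expect_equal(quaternion_to_rotation(rotation_to_quaternion(R)), R,
                 tolerance = 1e-12)
  }
  expect_error(nail_pose(diag(3) * 1.01), "orthonormal")
})
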