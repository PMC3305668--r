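# detection of lens regions and landmark extraction

test_that("both holes are detected near their ground-truth centroids", {
  fx <- make_fixture("mild-oblique", seed = 21)
  det <- detect_lens_regions(fx$image$pixels, fx$camera)
  expect_length(det, 2L)
  gts <- fx$image$ground_truth_contours
  for (d in det) {
    cd <- colMeans(d$points)
    best <- min(vapply(gts, function(g) sqrt(sum((colMeans(g$points) - cd)^2)),
                       numeric(1)))
    expect_lt(best, 2)
  }
})

test_that("blank and screw-occluded images signal as specified", {
  blank <- matrix(1, 120, 120)
  expect_error(detect_lens_regions(blank), class = "nailguide_no_hole")
  fx <- make_fixture("one-screw-inserted", seed = 6)
  expect_warning(
    det <- detect_lens_regions(fx$image$pixels, fx$camera),
    class = "nailguide_occluded_hole"
  )
  expect_length(det, 1L)
})

test_that("landmarks extracted from analytic contours match the forward model", {
  cam <- scene_camera(); nl <- scene_nail()
  for (seed in c(2, 7, 9)) {
    pose <- scene_pose(seed)
    for (k in 1:2) {
      lc <- lens_contour(cam, nl, pose, k)
      lm <- extract_landmarks(lens_contour_object(lc$points))
      vl <- virtual_landmarks(cam, nl, pose, k)
      expect_false(lm$is_circular)
      expect_lt(landmark_max_err(lm, vl), 0.5)
      # apexes sit on opposite sides of the tip chord
      s1 <- nailguide:::chord_side(lm$tips[1, ], lm$tips[2, ], lm$apexes[1, ])
      s2 <- nailguide:::chord_side(lm$tips[1, ], lm$tips[2, ], lm$apexes[2, ])
      expect_true(s1 * s2 < 0)
    }
  }
})

test_that("apex is the arg-max of chord distance over the arc points", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(4)
  lc <- lens_contour(cam, nl, pose, 1)
  lm <- extract_landmarks(lens_contour_object(lc$points))
  # brute-force scan over the original contour
  d_all <- nailguide:::chord_distance(lc$points, lm$tips[1, ], lm$tips[2, ])
  best <- max(d_all)
  d_apex <- max(nailguide:::chord_distance(lm$apexes, lm$tips[1, ], lm$tips[2, ]))
  expect_gt(d_apex, best - 0.1)
})

test_that("circular contours return a circle fit with accurate radius", {
  truth <- ellipse_conic(c(200, 150), c(24.5, 24.5))
  pts <- ellipse_points(truth, seq(0, 2 * pi, length.out = 181)[-181])
  lm <- extract_landmarks(lens_contour_object(pts))
  expect_true(lm$is_circular)
  expect_null(lm$tips)
  expect_equal(lm$circle_radius_px, 24.5, tolerance = 0.5)
  expect_equal(lm$circle_center_px, c(200, 150), tolerance = 0.5)
})

test_that("extract_landmarks rejects tiny contours", {
  expect_error(extract_landmarks(lens_contour_object(cbind(1:10, 1:10 + 1))),
               "20 points")
})

test_that("landmark extraction is stable under contour noise", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(8)
  lc <- lens_contour(cam, nl, pose, 1)
  vl <- virtual_landmarks(cam, nl, pose, 1)
  set.seed(99)
  tip_err2 <- c()
  for (trial in 1:100) {
    noisy <- lc$points + matrix(stats::rnorm(length(lc$points), 0, 0.5),
                                ncol = 2)
    lm <- tryCatch(extract_landmarks(lens_contour_object(noisy)),
                   error = function(e) NULL)
    if (is.null(lm) || lm$is_circular) next
    d <- rowSums((lm$tips[order(lm$tips[, 1]), ] -
                    vl$tips[order(vl$tips[, 1]), ])^2)
    tip_err2 <- c(tip_err2, d)
  }
  expect_gt(length(tip_err2), 150)
  expect_lt(sqrt(mean(tip_err2)), 1.5)
})

test_that("detection recall holds across seeded noisy fixtures", {
  # spec band scaled down to 30 fixtures to keep the default run fast
  hits <- 0L; total <- 0L
  for (seed in 101:130) {
    fx <- make_fixture("mild-oblique", seed = seed, noise_sigma = 0.02)
    total <- total + 1L
    det <- tryCatch(
      suppressWarnings(detect_lens_regions(fx$image$pixels, fx$camera)),
      error = function(e) NULL)
    if (!is.null(det) && length(det) == 2L) hits <- hits + 1L
  }
  expect_gte(hits / total, 0.98)
})
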