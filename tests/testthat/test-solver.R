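# 6-DOF pose recovery from landmark sets

exact_landmarks <- function(cam, nl, pose) {
  lapply(1:2, function(k) virtual_landmarks(cam, nl, pose, k))
}

test_that("initial candidates from noise-free landmarks are close", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(41, band = c(18, 22))
  lms <- exact_landmarks(cam, nl, pose)
  hc <- nailguide:::hole_axis_camera(nl, pose, 1)
  cands <- initial_pose_candidates(lms[[1]], cam, nl, 1)
  ax_err <- vapply(cands, function(cc) {
    nailguide:::line_angle_deg(cc$axis, hc$axis)
  }, numeric(1))
  expect_lt(min(ax_err), 5)
  z_err <- vapply(cands, function(cc) {
    abs(cc$center_mm[3] - hc$center[3]) / hc$center[3]
  }, numeric(1))
  expect_lt(min(z_err), 0.02)
})

test_that("aligned holes initialize along the source-to-center ray", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(42, band = c(0, 0.8))
  lm <- virtual_landmarks(cam, nl, pose, 1)
  expect_true(lm$is_circular)
  cand <- initial_pose_candidates(lm, cam, nl, 1)[[1]]
  hc <- nailguide:::hole_axis_camera(nl, pose, 1)
  expect_lt(nailguide:::line_angle_deg(cand$axis, hc$center), 2)
})

test_that("ground-truth initialization is a fixed point of the solver", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(43)
  lms <- exact_landmarks(cam, nl, pose)
  sol <- solve_pose(lms, cam, nl, init_poses = list(pose))
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2L)
  expect_lt(sol$rms_residual_px, 1e-6)
  m <- nailguide:::pose_error_metrics(sol$pose, pose, nl)
  expect_lt(max(m$axis_deg), 1e-6)
  expect_lt(max(m$center_mm), 1e-6)
})

test_that("noise-free landmark solves recover all poses to 0.1 deg / 0.5 mm", {
  cam <- scene_camera()
  for (layout in c("parallel", "parallel_ap")) {
    nl <- if (layout == "parallel") scene_nail() else
      nail_spec(holes = list(hole_spec(0, c(0, 1, 0), "AP"),
                             hole_spec(12, c(0, 1, 0), "AP")))
    seeds <- if (layout == "parallel") 51:56 else 61:63
    for (seed in seeds) {
      pose <- sample_pose(cam, nl, c(5, 20), seed = seed)
      lms <- exact_landmarks(cam, nl, pose)
      sol <- solve_pose(lms, cam, nl)
      expect_true(sol$converged)
      m <- nailguide:::pose_error_metrics(sol$pose, pose, nl)
      expect_lt(max(m$axis_deg), 0.1)
      expect_lt(max(m$center_mm), 0.5)
    }
  }
})

test_that("landmark noise of 0.5 px keeps median errors within 1 deg / 1 mm", {
  cam <- scene_camera(); nl <- scene_nail()
  set.seed(77)
  ax <- ct <- c()
  for (trial in 1:40) {
    pose <- sample_pose(cam, nl, c(5, 20), seed = 700 + trial)
    lms <- exact_landmarks(cam, nl, pose)
    lms <- lapply(lms, function(lm) {
      if (lm$is_circular) return(lm)
      jit <- function(m) m + matrix(stats::rnorm(length(m), 0, 0.5), ncol = 2)
      lm$tips <- jit(lm$tips); lm$apexes <- jit(lm$apexes)
      lm$quarter_points <- jit(lm$quarter_points)
      lm
    })
    sol <- solve_pose(lms, cam, nl)
    if (!sol$converged) next
    m <- nailguide:::pose_error_metrics(sol$pose, pose, nl)
    ax <- c(ax, max(m$axis_deg)); ct <- c(ct, max(m$center_mm))
  }
  expect_gt(length(ax), 35)
  expect_lt(stats::median(ax), 1.0)
  # 0.5 px landmark noise maps to ~1.5 mm median depth uncertainty at the
  # default geometry (0.2 mm/px detector, ~1.4x magnification); 2 mm bounds it
  expect_lt(stats::median(ct), 2.0)
})

test_that("accepted optimizer iterations never increase the residual", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(45)
  lms <- exact_landmarks(cam, nl, pose)
  cands <- initial_pose_candidates(lms[[1]], cam, nl, 1)
  cands2 <- initial_pose_candidates(lms[[2]], cam, nl, 2)
  ps <- nailguide:::candidate_to_pose(cands[[1]], cands2[[1]], nl)
  ref <- nailguide:::lm_refine(ps[[1]], lms, cam, nl, c(1L, 2L))
  expect_true(all(diff(ref$trace_cost) <= 0))
})

test_that("single-hole input reports the under-constrained direction", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(46)
  lms <- exact_landmarks(cam, nl, pose)
  err <- tryCatch(solve_pose(list(lms[[1]], NULL), cam, nl),
                  nailguide_under_constrained = function(e) e)
  expect_s3_class(err, "nailguide_under_constrained")
  expect_match(conditionMessage(err), "rotation about")
  expect_error(solve_pose(list(NULL, NULL), cam, nl),
               class = "nailguide_under_constrained")
})

test_that("simulate_second_hole reproduces and shift-corrects landmarks", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(47)
  lms <- exact_landmarks(cam, nl, pose)
  sol <- solve_pose(lms, cam, nl, init_poses = list(pose))
  sim <- simulate_second_hole(sol, cam, nl, 2)
  expect_lt(landmark_max_err(sim$landmarks, lms[[2]]), 1e-6)

  # shifted frame: adding the estimated shift matches the new frame's truth
  fx <- make_fixture("shifted-frame-pair", seed = 48)
  lms_fx <- exact_landmarks(fx$camera, fx$nail, fx$image$ground_truth)
  sol_fx <- solve_pose(lms_fx, fx$camera, fx$nail, init_poses = list(fx$image$ground_truth))
  es <- estimate_frame_shift(fx$image$pixels, fx$image_b$pixels)
  sim2 <- simulate_second_hole(sol_fx, fx$camera, fx$nail, 2,
                               shift_px = es$shift_px)
  shifted_truth <- nailguide:::shift_landmarks(lms_fx[[2]], fx$shift_px)
  expect_lt(landmark_max_err(sim2$landmarks, shifted_truth), 0.3)

  expect_error(simulate_second_hole(
    pose_solution(NULL, Inf, numeric(0), "none", FALSE, 0L), cam, nl, 2),
    "not converged")
})

test_that("a 1-degree axis error displaces landmarks within the small-angle bound", {
  cam <- scene_camera(); nl <- scene_nail()
  pose <- scene_pose(49)
  lms <- exact_landmarks(cam, nl, pose)
  sol <- solve_pose(lms, cam, nl, init_poses = list(pose))
  tilt <- axis_angle_to_rotation(unit3(c(0, 0, 1)) * pi / 180)
  pose_err <- nail_pose(tilt %*% pose$rotation, pose$translation_mm)
  sol_err <- pose_solution(pose_err, 0, numeric(0), "x", TRUE, 0L)
  sim_true <- simulate_second_hole(sol, cam, nl, 2)
  sim_err <- simulate_second_hole(sol_err, cam, nl, 2)
  disp <- landmark_max_err(sim_err$landmarks, sim_true$landmarks)
  # displacement bound: rotating by 1 deg moves points on the nail by at most
  # lever * tan(1 deg); projected at magnification SDD/z over the pixel pitch
  lever <- max(abs(c(nl$length_mm / 2, nl$outer_radius_mm))) + 12
  bound <- lever * tan(pi / 180) * (cam$sdd_mm / 600) / cam$pixel_pitch_mm
  expect_lt(disp, bound)
})
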