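# Shared scene builders and small numeric helpers for the suite.
# Everything is generated in code; no stored fixtures.

test_camera <- function() {
  camera_model(sdd_mm = 1000, pixel_pitch_mm = 0.5,
               principal_point_px = c(512, 512),
               image_size_px = c(1024, 1024))
}

scene_camera <- function() nailguide:::fixture_camera()
scene_nail <- function(layout = "parallel") nailguide:::fixture_nail(layout)

scene_pose <- function(seed, band = c(5, 20), camera = scene_camera(),
                       nail = scene_nail()) {
  sample_pose(camera, nail, band, seed = seed)
}

# distance from each point (rows) to a closed polyline
dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- poly[nxt, 1]; by <- poly[nxt, 2]
  dx <- bx - ax; dy <- by - ay
  len2 <- pmax(dx^2 + dy^2, 1e-300)
  vapply(seq_len(nrow(pts)), function(i) {
    t <- ((pts[i, 1] - ax) * dx + (pts[i, 2] - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    min(sqrt((ax + t * dx - pts[i, 1])^2 + (ay + t * dy - pts[i, 2])^2))
  }, numeric(1))
}

hausdorff_px <- function(a, b) {
  max(max(dist_to_polygon(a, b)), max(dist_to_polygon(b, a)))
}

# landmark-vector difference that tolerates the canonical tip-order tie
landmark_max_err <- function(lm, vl) {
  a <- landmark_vector(lm)
  b <- landmark_vector(vl)
  if (lm$is_circular || vl$is_circular) return(max(abs(a - b)))
  if (sum((a[1:4] - b[c(3, 4, 1, 2)])^2) < sum((a[1:4] - b[1:4])^2)) {
    b <- landmark_vector(nailguide:::flip_landmark_order(vl))
  }
  max(sqrt(rowSums(matrix(a - b, ncol = 2, byrow = TRUE)^2)))
}

# render + detect + landmark sets ordered to match hole indices
detect_ordered_landmarks <- function(fx) {
  det <- detect_lens_regions(fx$image$pixels, fx$camera)
  rim_ratio <- nailguide:::rim_offset_mm(fx$nail) / fx$nail$hole_radius_mm
  lms <- lapply(det, extract_landmarks, rim_ratio = rim_ratio)
  gt1 <- fx$image$ground_truth_contours[[1]]
  if (!is.null(gt1) && length(det) == 2) {
    g1 <- colMeans(gt1$points)
    d1 <- sum((colMeans(det[[1]]$points) - g1)^2)
    d2 <- sum((colMeans(det[[2]]$points) - g1)^2)
    if (d1 > d2) lms <- lms[2:1]
  }
  lms
}

solve_fixture <- function(fx) {
  lms <- detect_ordered_landmarks(fx)
  solve_pose(lms, fx$camera, fx$nail)
}

pose_errors <- function(sol, fx) {
  nailguide:::pose_error_metrics(sol$pose, fx$image$ground_truth, fx$nail)
}
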