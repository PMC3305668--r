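# conic container and algebraic least-squares fitting

test_that("conic coefficient and ellipse forms agree under round trip", {
  set.seed(11)
  for (i in 1:25) {
    ctr <- runif(2, -200, 1200)
    ax <- sort(runif(2, 0.5, 300), decreasing = TRUE)
    th <- runif(1, 0, pi)
    cc <- ellipse_conic(ctr, ax, th)
    expect_equal(cc$center_px, ctr, tolerance = 1e-9)
    expect_equal(cc$semi_axes_px, ax, tolerance = 1e-9)
    back <- conic2d(cc$coef)
    expect_equal(back$center_px, ctr, tolerance = 1e-9)
    expect_equal(abs(sum(back$coef * cc$coef)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(cc$coef^2)), 1, tolerance = 1e-12)
    # a >= b and interior negative
    expect_gte(cc$semi_axes_px[1], cc$semi_axes_px[2])
    expect_lt(conic_eval(cc, ctr), 0)
  }
})

test_that("fit_conic recovers exact ellipse parameters from noiseless samples", {
  set.seed(3)
  for (i in 1:10) {
    ctr <- runif(2, 100, 900)
    ax <- sort(runif(2, 5, 80), decreasing = TRUE)
    th <- runif(1, 0, pi)
    truth <- ellipse_conic(ctr, ax, th)
    pts <- ellipse_points(truth, seq(0, 2 * pi, length.out = 51)[-51])
    fit <- fit_conic(pts)
    expect_equal(fit$center_px, ctr, tolerance = 1e-6)
    expect_equal(fit$semi_axes_px, ax, tolerance = 1e-6)
    d <- min(sqrt(sum((fit$coef - truth$coef)^2)),
             sqrt(sum((fit$coef + truth$coef)^2)))
    expect_lt(d, 1e-6)
  }
})

test_that("fit_conic on circle samples gives equal semi-axes", {
  pts <- ellipse_points(ellipse_conic(c(10, -4), c(7, 7)),
                        seq(0, 2 * pi, length.out = 33)[-33])
  fit <- fit_conic(pts)
  expect_equal(fit$semi_axes_px[1], fit$semi_axes_px[2], tolerance = 1e-9)
})

test_that("fit_conic rejects degenerate inputs", {
  expect_error(fit_conic(cbind(1:4, 1:4)), "at least 5")
  expect_error(fit_conic(cbind(1:9, 2 * (1:9) + 3)), "collinear")
  expect_error(fit_conic(matrix(rep(c(1, 2), each = 6), ncol = 2)))
})

test_that("fit_conic is invariant to ordering and equivariant under scaling", {
  set.seed(5)
  truth <- ellipse_conic(c(50, 80), c(20, 9), 0.7)
  pts <- ellipse_points(truth, sort(runif(40, 0, 2 * pi)))
  f1 <- fit_conic(pts)
  f2 <- fit_conic(pts[sample(nrow(pts)), ])
  d <- min(sqrt(sum((f1$coef - f2$coef)^2)), sqrt(sum((f1$coef + f2$coef)^2)))
  expect_lt(d, 1e-9)
  # uniform scaling of the frame scales the fitted ellipse accordingly
  f3 <- fit_conic(pts * 3)
  expect_equal(f3$center_px, f1$center_px * 3, tolerance = 1e-6)
  expect_equal(f3$semi_axes_px, f1$semi_axes_px * 3, tolerance = 1e-6)
})
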