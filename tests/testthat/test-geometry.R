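test_that("ellipse eccentricity follows the closed form and its symmetries", {
  expect_equal(ellipse_eccentricity(1, 0.32), 0.947418, tolerance = 5e-6)
  expect_identical(ellipse_eccentricity(3, 3), 0)
  # scale invariance and argument-order invariance
  expect_equal(ellipse_eccentricity(2, 0.64), ellipse_eccentricity(1, 0.32))
  expect_equal(ellipse_eccentricity(0.32, 1), ellipse_eccentricity(1, 0.32))
  expect_error(ellipse_eccentricity(-1, 1), "positive")
  expect_error(ellipse_eccentricity(1, 0), "positive")
})

test_that("ellipse constructor normalises orientation and axis order", {
  e <- ellipse(0, 0, a = 1, b = 2, theta = 0.3)
  expect_gte(e$a, e$b)
  expect_equal(e$a, 2)
  expect_equal(e$theta, (0.3 + pi / 2) %% pi)
  expect_true(ellipse(0, 0, 1, 1, -0.5)$theta >= 0)
  expect_error(ellipse(0, 0, 0, 1), "positive")
})

test_that("conic/parametric conversions invert each other", {
  # unit circle maps to the expected coefficients up to scale
  v <- as.numeric(as_conic(ellipse(0, 0, 1, 1)))
  expect_equal(v / v[1], c(1, 0, 1, 0, 0, -1), tolerance = 1e-12)
  expect_equal(v[2]^2 - 4 * v[1] * v[3], -1, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    e <- random_ellipse()
    e2 <- as_ellipse(as_conic(e))
    expect_equal(unlist(e2[c("cx", "cy", "a", "b")]),
                 unlist(e[c("cx", "cy", "a", "b")]), tolerance = 1e-9)
    dth <- abs(e2$theta - e$theta) %% pi
    expect_lt(min(dth, pi - dth) * (e$a - e$b), 1e-8)
  }
})

test_that("conic coefficients of an ellipse satisfy the boundary equation", {
  e <- ellipse(2, 3, 1, 0.32, 30 * pi / 180)
  v <- as.numeric(as_conic(e))
  bp <- boundary_points(e, seq(0, 2 * pi, length.out = 100))
  resid <- v[1] * bp[, 1]^2 + v[2] * bp[, 1] * bp[, 2] + v[3] * bp[, 2]^2 +
    v[4] * bp[, 1] + v[5] * bp[, 2] + v[6]
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("non-ellipse conics are rejected", {
  expect_false(is_ellipse(conic(1, 0, -1, 0, 0, -1)))   # hyperbola
  expect_false(is_ellipse(conic(1, 2, 1, 0, 0, -1)))    # parabola
  expect_error(as_ellipse(conic(1, 0, -1, 0, 0, -1)), "not an ellipse")
  expect_error(conic_eccentricity(conic(1, 0, -1, 0, 0, -1)), "not an ellipse")
  # real ellipse coefficients always pass the discriminant test
  set.seed(7)
  for (i in 1:100) expect_true(is_ellipse(as_conic(random_ellipse())))
})

test_that("eccentricity from conic coefficients matches the geometric value", {
  expect_equal(conic_eccentricity(conic(2, 0, 2, 0, 0, -1)), 0)
  e <- ellipse(-1, 4, 1, 0.32, 1.1)
  expect_equal(conic_eccentricity(as_conic(e)), 0.947418, tolerance = 5e-6)
  # invariance under rescaling by a negative factor (eta sign rule)
  v <- as.numeric(as_conic(e)) * -7
  expect_equal(conic_eccentricity(do.call(conic, as.list(v))),
               conic_eccentricity(as_conic(e)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:1000) {
    e <- random_ellipse()
    expect_equal(conic_eccentricity(as_conic(e)),
                 ellipse_eccentricity(e$a, e$b), tolerance = 1e-9)
  }
})

test_that("point eccentricity is the eccentricity-scaled axis-distance ratio", {
  e <- ellipse(0, 0, 1, 0.32, 0)
  eps <- ellipse_eccentricity(1, 0.32)
  expect_equal(point_eccentricity(c(1, 0), e), eps)        # major vertex
  expect_equal(point_eccentricity(c(0, 0.32), e), 0)       # minor vertex
  expect_identical(point_eccentricity(c(0, 0), e), 0)      # centre convention
  # hand evaluation at the parametric 45-degree point
  expect_equal(point_eccentricity(c(0.70711, 0.226274), e), 0.717741,
               tolerance = 1e-5)
  # xi depends only on direction from the centre, and respects the pose
  set.seed(3)
  for (i in 1:50) {
    e <- random_ellipse()
    d <- runif(2, -1, 1)
    p1 <- c(e$cx, e$cy) + 0.3 * d
    p2 <- c(e$cx, e$cy) + 4.7 * d
    x1 <- point_eccentricity(p1, e)
    expect_equal(x1, point_eccentricity(p2, e), tolerance = 1e-12)
    expect_gte(x1, 0)
    expect_lte(x1, ellipse_eccentricity(e$a, e$b) + 1e-12)
  }
})

test_that("mean point eccentricity averages per-point values", {
  e <- ellipse(0, 0, 1, 0.32, 0)
  eps <- ellipse_eccentricity(1, 0.32)
  verts <- rbind(c(1, 0), c(-1, 0))
  expect_equal(mean_point_eccentricity(verts, e), eps)
  expect_error(point_eccentricity(matrix(numeric(0), 0, 2), e), "at least")
})

test_that("orthogonal distance matches closed forms and a dense oracle", {
  ec <- ellipse(1, 2, 3, 3)
  expect_equal(orthogonal_distance(c(1, 7), ec), 2)       # outside circle
  expect_equal(orthogonal_distance(c(2, 2), ec), 2)       # inside circle
  e <- ellipse(0, 0, 1, 0.32, 0)
  expect_equal(orthogonal_distance(c(0, 0), e), 0.32)     # centre -> minor
  set.seed(5)
  for (i in 1:100) {
    e <- random_ellipse()
    p <- c(e$cx, e$cy) + runif(2, -2 * e$a, 2 * e$a)
    expect_equal(orthogonal_distance(p, e), dense_distance(p, e),
                 tolerance = 1e-6 * e$a)
  }
})

test_that("orthogonal distance respects the ellipse's reflective symmetries", {
  e <- ellipse(0, 0, 2, 0.7, 0)
  p <- c(1.3, 0.4)
  d <- orthogonal_distance(p, e)
  for (q in list(c(-p[1], p[2]), c(p[1], -p[2]), -p))
    expect_equal(orthogonal_distance(q, e), d, tolerance = 1e-12)
})

test_that("rmse is the root mean squared orthogonal distance", {
  e <- ellipse(1, -1, 2, 1, 0.5)
  on <- boundary_points(e, seq(0, 2 * pi, length.out = 40))
  expect_lt(rmse_ellipse(on, e), 1e-9)
  p <- c(3.7, 0.2)
  expect_equal(rmse_ellipse(p, e), orthogonal_distance(p, e))
  set.seed(9)
  pts <- matrix(rnorm(40, sd = 2), ncol = 2)
  d <- orthogonal_distance(pts, e)
  expect_gte(rmse_ellipse(pts, e), mean(d))   # Jensen
})
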