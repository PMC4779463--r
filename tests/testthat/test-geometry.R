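test_that("initial trabecula is a mirror-symmetric rectangle with 12 points per side", {
  g <- build_initial_trabecula(1.0, 0.2, 0)
  expect_equal(nrow(g$left_points), 12L)
  expect_equal(nrow(g$right_points), 12L)
  expect_equal(central_width(g), 0.2)
  expect_equal(g$left_points[, 1], -g$right_points[, 1])
  expect_equal(g$left_points[, 2], g$right_points[, 2])
  expect_equal(g$left_points[, 2], ((1:12) - 0.5) / 12)
  expect_equal(unname(point_spacing(g)), rep(1 / 12, 2))
  expect_equal(g$left_span, c(0, 1))
})

test_that("validation geometry is the inclined 0.92 mm trabecula", {
  g <- build_initial_trabecula(0.92, 0.2, 30 * pi / 180)
  # bottom edge centred at the origin, axis at 30 degrees to the vertical;
  # the first point pair sits half a cell (L/24) up the axis
  start <- (g$left_points[1, ] + g$right_points[1, ]) / 2
  end <- (g$left_points[12, ] + g$right_points[12, ]) / 2
  expect_equal(start, 0.92 / 24 * c(sin(pi / 6), cos(pi / 6)),
               tolerance = 1e-12)
  axis <- end - start
  expect_equal(atan2(axis[1], axis[2]), 30 * pi / 180, tolerance = 1e-12)
  expect_equal(sqrt(sum(axis^2)), 0.92 * 11 / 12, tolerance = 1e-12)
})

test_that("invalid dimensions are rejected", {
  expect_error(build_initial_trabecula(0, 0.2), "invalid geometry")
  expect_error(build_initial_trabecula(1, -1), "invalid geometry")
  expect_error(build_initial_trabecula(1, 0.2, pi / 2), "invalid geometry")
})

test_that("geometry round-trips through its characteristic points", {
  g <- build_initial_trabecula()
  g2 <- geometry_from_points(g$left_points, g$right_points,
                             width_initial = g$width_initial)
  expect_equal(central_width(g2), central_width(g), tolerance = 1e-9)
  expect_equal(g2$left_points, g$left_points)
})

test_that("rigid offset of one spline widens the section by the offset", {
  g <- build_initial_trabecula()
  right <- g$right_points
  right[, 1] <- right[, 1] + 0.01
  g2 <- geometry_from_points(g$left_points, right)
  expect_equal(central_width(g2), 0.21, tolerance = 1e-12)
})

test_that("horizontal scaling scales the central width linearly", {
  g <- build_initial_trabecula()
  g2 <- geometry_from_points(cbind(2 * g$left_points[, 1], g$left_points[, 2]),
                             cbind(2 * g$right_points[, 1], g$right_points[, 2]))
  expect_equal(central_width(g2), 0.4, tolerance = 1e-12)
})

test_that("crossed splines are rejected as degenerate", {
  g <- build_initial_trabecula()
  right <- g$right_points
  right[, 1] <- right[, 1] - 0.3   # pushes the right spline past the left
  expect_error(geometry_from_points(g$left_points, right), "degenerate")
  expect_error(geometry_from_points(g$left_points[1:7, ], g$right_points[1:7, ]),
               "12 characteristic points")
})
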