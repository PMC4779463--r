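test_that("surface displacement follows the capped velocity rule", {
  p <- remodelling_params()  # published defaults: V_target 5e-8, band 4.8/5.2
  g <- build_initial_trabecula()
  move_first <- function(V) {
    v <- rep(p$V_target, 24); v[1] <- V
    upd <- update_positions(g$left_points, g$right_points, v, p)
    upd$displacements[1]
  }
  # inside the dead band: no movement
  expect_equal(move_first(5e-8), 0)
  expect_equal(move_first(5.19e-8), 0)
  expect_equal(move_first(4.81e-8), 0)
  # deposition at twice the apposition threshold: 0.005 * V / V_target
  expect_equal(move_first(1.04e-7), 0.005 * 1.04e-7 / 5e-8)
  expect_equal(move_first(1.04e-7), 0.0104)
  # the 0.05 mm cap
  expect_equal(move_first(100 * 5e-8), 0.05)
  # resorption moves inward (negative outward displacement)
  expect_equal(move_first(2.5e-8), -0.005 * 0.5)
})

test_that("no single-iteration displacement ever exceeds the cap", {
  p <- remodelling_params()
  g <- build_initial_trabecula()
  set.seed(7)
  for (i in 1:20) {
    v <- 10^runif(24, -9, -4)
    upd <- update_positions(g$left_points, g$right_points, v, p)
    expect_lte(max(abs(upd$displacements)), 0.05)
    # apposition points moved outward, resorption inward, band points fixed
    outward <- upd$displacements > 0
    expect_true(all(v[outward] >= p$V_apposition))
    inward <- upd$displacements < 0
    expect_true(all(v[inward] <= p$V_resorption))
  }
})

test_that("velocities inside the dead band leave the geometry a fixed point", {
  p <- remodelling_params()
  g <- build_initial_trabecula()
  v <- runif(24, p$V_resorption + 1e-12, p$V_apposition - 1e-12)
  upd <- update_positions(g$left_points, g$right_points, v, p)
  expect_equal(upd$left_points, g$left_points)
  expect_equal(upd$right_points, g$right_points)
})

test_that("crossing surfaces abort with a degenerate-geometry error", {
  g <- build_initial_trabecula(width = 0.05)
  p <- remodelling_params(displacement_increment = 0.06,
                          max_displacement = 0.2)
  # outward growth is safe ...
  expect_no_error(update_positions(g$left_points, g$right_points,
                                   rep(p$V_target * 20, 24), p))
  # ... but resorbing more than the half width crosses the surfaces
  expect_error(update_positions(g$left_points, g$right_points,
                                rep(p$V_resorption * 0.9, 24), p),
               "degenerate")
})

test_that("characteristic velocity is the mean over elements of time medians", {
  centroids <- cbind(c(0, 0.01, 0.5), c(0, 0.01, 0.5))
  # element 1: ramp 0..9; element 2: constant 2; element 3: far away
  qmag <- rbind(0:9, rep(2, 10), rep(100, 10))
  res <- synthetic_result(centroids, qmag)
  expect_equal(characteristic_velocity(res, c(0, 0), radius = 0.1), (4.5 + 2) / 2)
  expect_equal(characteristic_velocity(res, c(0.5, 0.5), radius = 0.01), 100)
  u <- 3e-7
  res2 <- synthetic_result(cbind(0, 0), matrix((0:9) * u, 1))
  expect_equal(characteristic_velocity(res2, c(0, 0), radius = 1), 4.5 * u)
  expect_error(characteristic_velocity(res, c(5, 5), radius = 0.1), "empty")
  # alternative reading: peak over time, median over elements
  expect_equal(characteristic_velocity(res, c(0, 0), radius = 0.1,
                                       statistic = "peak_time_median_elems"),
               median(c(9, 2)))
})

test_that("symmetric axial load gives mirror-equal characteristic velocities", {
  cs <- compression_solve()
  p <- remodelling_params()
  v <- porotrab:::characteristic_velocities(cs$result, cs$geometry, p)
  expect_equal(v[1:12], v[13:24], tolerance = 1e-8)
  expect_true(all(v > 0))
})

test_that("the 5% of central width completion rule is boundary inclusive", {
  g <- build_initial_trabecula()
  pts <- rbind(g$left_points, g$right_points)
  expect_true(check_convergence(pts, pts, 0.2))
  moved <- pts; moved[5, 1] <- moved[5, 1] + 0.011
  expect_false(check_convergence(pts, moved, 0.2))
  moved2 <- pts; moved2[, 1] <- moved2[, 1] + 0.01
  expect_true(check_convergence(pts, moved2, 0.2))
})

test_that("parameter validation enforces the band ordering and caps", {
  expect_error(remodelling_params(V_resorption = 6e-8), "V_resorption")
  expect_error(remodelling_params(displacement_increment = 0.06))
  p <- remodelling_params(V_target = 1e-8)
  expect_equal(p$V_apposition, 1.04e-8)
  expect_equal(p$V_resorption, 0.96e-8)
})

test_that("a short remodelling run is deterministic and respects the cap", {
  mat <- remodelling_material()
  g <- build_initial_trabecula()
  pulse <- load_pulse(2 * f_target(mat), theta = pi)
  p <- remodelling_params(V_target = 2e-8, max_iterations = 3L)
  h1 <- run_remodelling(g, mat, pulse, p, h = 0.05, h_plate = 0.15)
  h2 <- run_remodelling(g, mat, pulse, p, h = 0.05, h_plate = 0.15)
  expect_null(h1$error)
  expect_identical(h1$velocities, h2$velocities)
  expect_identical(h1$final_geometry$left_points, h2$final_geometry$left_points)
  expect_lte(max(abs(h1$displacements)), 0.05)
  expect_equal(h1$iterations, 3L)
})
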