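test_that("study presets enumerate the published load plan", {
  p42 <- study_plan("reference42")
  expect_equal(nrow(p42$scenarios), 42L)
  expect_equal(length(unique(p42$scenarios$theta)), 14L)
  expect_equal(p42$h, 0.015)
  p70 <- study_plan("full70")
  expect_equal(nrow(p70$scenarios), 70L)
  expect_setequal(unique(p70$scenarios$F_mult), c(0.5, 0.75, 1, 1.5, 2))
  pc <- study_plan("coarse")
  expect_gte(length(unique(pc$scenarios$theta)), 6L)
  expect_true(all(pc$scenarios$theta >= 0 & pc$scenarios$theta <= pi))
  expect_error(study_plan("custom", angles = c(-0.1), amplitudes = 1))
})

test_that("the fit domains follow the published angle windows", {
  expect_true(all(porotrab:::in_fit_domain(c(0, 6 * pi / 16, 10 * pi / 16, pi))))
  expect_false(any(porotrab:::in_fit_domain(c(7 * pi / 16, pi / 2, 9 * pi / 16))))
  expect_true(all(porotrab:::in_quasilinear_domain(c(5 * pi / 16, 11 * pi / 16))))
  expect_false(any(porotrab:::in_quasilinear_domain(c(6 * pi / 16, 10 * pi / 16))))
})

ministudy <- function() {
  fix_get("ministudy", function() {
    plan <- study_plan("custom",
                       angles = c(1, 3, 13, 15) * pi / 16,
                       amplitudes = c(0.5, 1, 2),
                       h = 0.05, h_plate = 0.15,
                       max_iterations = 30L, calibrate = TRUE)
    run_study(plan)
  })
}

test_that("a miniature sweep produces records, laws and on-disk tables", {
  st <- ministudy()
  expect_s3_class(st, "study_result")
  expect_equal(nrow(st$results), 12L)
  expect_true(all(is.na(st$results$error)))
  expect_true(all(is.finite(st$results$R_A)))
  expect_true(all(st$results$R_A > 0))
  # reorientation follows the load side: tension angles tilt positive
  mean_t <- mean(st$results$dphi[st$results$theta < pi / 2])
  mean_c <- mean(st$results$dphi[st$results$theta > pi / 2])
  expect_gt(mean_t, 0)
  expect_lt(mean_c, 0)
  gl <- glance(st)
  expect_true(all(unlist(gl[grepl("r2", names(gl))]) <= 1))
  out <- file.path(tempdir(), "ministudy")
  write_study(st, out)
  eb <- read.csv(file.path(out, "equivalent_beams.csv"))
  expect_equal(nrow(eb), 12L)
  laws <- jsonlite::read_json(file.path(out, "laws.json"))
  expect_true(is.numeric(laws$b))
  expect_true(all(c("a", "b", "i", "j", "k_mean", "r2") %in% names(laws)))
})

test_that("history and mesh exports are well-formed text artefacts", {
  st <- ministudy()
  mat <- remodelling_material()
  g <- build_initial_trabecula()
  p <- st$params; p$max_iterations <- 2L
  hist <- run_remodelling(g, mat, load_pulse(2 * st$F_target, theta = pi), p,
                          h = 0.05, h_plate = 0.15)
  f <- tempfile(fileext = ".csv")
  write_history_csv(hist, f)
  hcsv <- read.csv(f)
  expect_setequal(names(hcsv), c("iteration", "side", "index", "x1", "x2",
                                 "V", "displacement"))
  expect_equal(max(hcsv$iteration), hist$iterations)
  vtk <- tempfile(fileext = ".vtk")
  mesh <- generate_mesh(g, h = 0.05, h_plate = 0.15)
  write_vtk(mesh, vtk, point_data = list(x1 = mesh$nodes[, 1]))
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET UNSTRUCTURED_GRID")
  expect_equal(sum(grepl("^CELLS", lines)), 1L)
})

test_that("calibration orders the band around the selected target", {
  p <- ministudy()$params
  expect_lt(p$V_resorption, p$V_target)
  expect_gt(p$V_apposition, p$V_target)
  expect_equal(p$V_apposition / p$V_target, 1.04, tolerance = 1e-9)
  cal <- attr(p, "calibration")
  expect_equal(length(cal$drift), length(cal$multipliers))
})
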