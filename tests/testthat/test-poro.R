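# Verification of the transient Biot solver against the 1D consolidation
# oracle and its basic structural properties (linearity, symmetry, boundary
# conditions).

terzaghi_setup <- function() {
  fix_get("terzaghi", function() {
    mat <- poroelastic_material(kappa = 1e-16)  # moderate time factor
    mesh <- rect_mesh(0, 0.1, 0, 1, 2, 50)
    pulse <- load_pulse(1, theta = pi, total_time = 1, increment = 0.01,
                        profile = "step")
    res <- solve_transient(mesh, mat, pulse, column_bcs(mesh, 1))
    list(material = mat, mesh = mesh, pulse = pulse, result = res)
  })
}

test_that("confined column pressures match the Terzaghi series within 1% L2", {
  tz <- terzaghi_setup()
  y <- tz$mesh$nodes[tz$mesh$sets$left, 2]
  for (k in c(30L, 60L, 100L)) {
    t <- tz$pulse$increment * k
    pref <- terzaghi_reference(1, tz$material, 1, times = t, y = y)$p[, 1]
    pnum <- tz$result$P[tz$mesh$sets$left, k]
    expect_lt(sqrt(sum((pnum - pref)^2) / sum(pref^2)), 0.01)
  }
})

test_that("Terzaghi reference has the undrained and drained limits", {
  mat <- poroelastic_material()
  tz0 <- terzaghi_reference(1, mat, 2, times = c(1e-9, 1e9))
  # t -> 0+: uniform Skempton-type pressure p0 away from the drained face
  interior <- tz0$y < 0.8
  expect_equal(tz0$p[interior, 1], rep(tz0$p0, sum(interior)),
               tolerance = 5e-3)  # series truncation at the t -> 0 step
  expect_equal(max(abs(tz0$p[, 2])), 0, tolerance = 1e-12)
  # 200-term evaluation is converged: doubling terms changes nothing
  a <- terzaghi_reference(1, mat, 1, times = 0.02, nterms = 200)$p
  b <- terzaghi_reference(1, mat, 1, times = 0.02, nterms = 400)$p
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("zero load produces identically zero fields", {
  cs <- compression_solve()
  pulse0 <- load_pulse(0, theta = pi)
  res <- solve_transient(cs$mesh, cs$material, pulse0,
                         standard_bcs(cs$mesh, pulse0))
  expect_equal(max(abs(res$U)), 0)
  expect_equal(max(abs(res$P)), 0)
  expect_equal(max(abs(res$qmag)), 0)
})

test_that("the coupled solution is linear in the load amplitude", {
  cs <- compression_solve()
  pulse2 <- load_pulse(2 * cs$pulse$F, theta = pi)
  res2 <- solve_transient(cs$mesh, cs$material, pulse2,
                          standard_bcs(cs$mesh, pulse2))
  expect_equal(res2$U, 2 * cs$result$U, tolerance = 1e-9)
  expect_equal(res2$P, 2 * cs$result$P, tolerance = 1e-9)
  expect_equal(res2$qmag, 2 * cs$result$qmag, tolerance = 1e-9)
})

test_that("tension and compression give equal-magnitude opposite pressures", {
  cs <- compression_solve()
  pulse_t <- load_pulse(cs$pulse$F, theta = 0)
  res_t <- solve_transient(cs$mesh, cs$material, pulse_t,
                           standard_bcs(cs$mesh, pulse_t))
  expect_equal(res_t$P, -cs$result$P, tolerance = 1e-6)
  expect_equal(res_t$qmag, cs$result$qmag, tolerance = 1e-6)
})

test_that("mirrored load angles theta and pi - theta mirror the flux field", {
  cs <- compression_solve()
  th <- 3 * pi / 16
  r1 <- solve_transient(cs$mesh, cs$material, load_pulse(0.7, theta = th),
                        standard_bcs(cs$mesh, load_pulse(0.7, theta = th)))
  r2 <- solve_transient(cs$mesh, cs$material, load_pulse(0.7, theta = pi - th),
                        standard_bcs(cs$mesh, load_pulse(0.7, theta = pi - th)))
  # mirror element mapping of the structured trabecula grid: column i -> nx-1-i
  nx <- cs$mesh$nx
  ntr <- sum(cs$mesh$region == "trabecula")
  cols <- (seq_len(ntr) - 1L) %% nx
  rows <- (seq_len(ntr) - 1L) %/% nx
  mirror <- rows * nx + (nx - 1L - cols) + 1L
  expect_equal(r1$qmag, r2$qmag[mirror, ], tolerance = 1e-5)
})

test_that("pressure is exactly zero on the free-flow lateral edges", {
  cs <- compression_solve()
  edge <- c(cs$mesh$sets$lateral_left, cs$mesh$sets$lateral_right)
  expect_equal(max(abs(cs$result$P[edge, ])), 0)
})

test_that("Darcy flux evaluates -(kappa/mu) grad p at element centroids", {
  cs <- compression_solve()
  res <- cs$result
  co <- cs$material$kappa / cs$material$mu
  # impose a linear pressure field p = x1 (gradient 1 N/mm^2 per mm)
  el <- cs$mesh$elems[res$elem_ids, , drop = FALSE]
  pe <- matrix(cs$mesh$nodes[el, 1], ncol = 4)
  qx <- -co * rowSums(res$dNdx * pe)
  qy <- -co * rowSums(res$dNdy * pe)
  expect_equal(qx, rep(-1e-5, nrow(el)), tolerance = 1e-9)
  expect_equal(max(abs(qy)), 0, tolerance = 1e-12)
  # accessor returns the stored per-element vector
  expect_equal(darcy_flux(res, 3, 5), res$q[3, , 5])
})

test_that("element fields satisfy the constitutive relations at centroids", {
  cs <- compression_solve()
  ef <- element_fields(cs$result, 5)
  mat <- cs$material
  expect_equal(ef$sigma_xx, ef$sigma_xx_eff - mat$alpha * ef$p)
  expect_equal(ef$zeta, ef$p / mat$M + mat$alpha * (ef$eps_xx + ef$eps_yy))
  # compression at peak: vertical total stress negative in the shaft
  expect_lt(median(ef$sigma_yy), 0)
})

test_that("spatial refinement converges the peak pressure field", {
  g <- build_initial_trabecula()
  mat <- poroelastic_material()
  pulse <- load_pulse(f_target(mat), theta = pi)
  m1 <- generate_mesh(g, h = 0.015, h_plate = 0.1, n_across = 14L)
  m2 <- generate_mesh(g, h = 0.0075, h_plate = 0.1, n_across = 28L)
  r1 <- solve_transient(m1, mat, pulse, standard_bcs(m1, pulse))
  r2 <- solve_transient(m2, mat, pulse, standard_bcs(m2, pulse))
  # coarse trabecula nodes are a subset of the fine ones
  key <- function(m) paste(round(m$nodes[m$sets$trab_nodes, 1], 9),
                           round(m$nodes[m$sets$trab_nodes, 2], 9))
  idx <- match(key(m1), key(m2))
  expect_false(anyNA(idx))
  p1 <- r1$P[m1$sets$trab_nodes, 5]
  p2 <- r2$P[m2$sets$trab_nodes, 5][idx]
  expect_lt(sqrt(sum((p1 - p2)^2) / sum(p2^2)), 0.02)
})
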