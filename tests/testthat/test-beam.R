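test_that("plate-equivalent rotational spring stiffness follows 4EI/t", {
  k <- spring_stiffness_from_plate(E = 18000, t = 0.5, d = 1, w = 1.4)
  I <- 1 * 1.4^3 / 12
  expect_equal(I, 0.2286667, tolerance = 1e-6)
  expect_equal(k, 4 * 18000 * I / 0.5, tolerance = 1e-12)
  expect_equal(k, 32928, tolerance = 1e-6)
  expect_equal(spring_stiffness_from_plate(w = 2.8), 8 * k, tolerance = 1e-9)
  expect_equal(spring_stiffness_from_plate(t = 1.0), k / 2, tolerance = 1e-9)
})

test_that("clamped and guided limits match closed-form Timoshenko deflections", {
  sec <- beam_section()
  EI <- sec$E * sec$I
  kGA <- sec$shear_correction * sec$G * sec$A
  H <- 1e-3
  pulse <- load_pulse(H, theta = pi / 2)  # transverse tip load
  # cantilever: clamped base, free tip
  sol <- solve_beam_static(sec, beam_support(k_bottom = Inf, k_top = 0,
                                             plates = NULL), pulse)
  expect_equal(sol$u[3, 1], H / (3 * EI) + H / kGA, tolerance = 1e-6)
  # guided: both end rotations clamped
  sol2 <- solve_beam_static(sec, beam_support(k_bottom = Inf, k_top = Inf,
                                              plates = NULL), pulse)
  expect_equal(sol2$u[3, 1], H / (12 * EI) + H / kGA, tolerance = 1e-6)
  # a very stiff spring approaches the clamped limit
  sol3 <- solve_beam_static(sec, beam_support(k_bottom = 1e12, k_top = 1e12,
                                              plates = NULL), pulse)
  expect_equal(sol3$u[3, 1], sol2$u[3, 1], tolerance = 1e-6)
})

test_that("axial load at the Mechanostat target gives the target strain", {
  sec <- beam_section()
  F <- f_target(poroelastic_material())
  st <- extract_beam_strains(
    solve_beam_static(sec, beam_support(), load_pulse(F, theta = 0)))
  expect_equal(st$eps_a, 1250e-6, tolerance = 0.05)  # small plate compliance
  expect_equal(st$eps_b, 0, tolerance = 1e-9)
  expect_equal(st$K_eps, 0, tolerance = 1e-6)
})

test_that("zero load gives the zero solution", {
  sol <- solve_beam_static(beam_section(), beam_support(),
                           load_pulse(0, theta = pi / 4))
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(max(abs(sol$rot)), 0)
})

test_that("section strains follow the fiber kinematics at Gauss point 2", {
  sec <- beam_section()
  chi <- 0.02
  # fabricated solution: pure curvature field psi = chi * s, no axial strain
  sol <- structure(list(u = matrix(0, 3, 2), rot = chi * c(0, 0.5, 1),
                        section = sec, support = NULL, pulse = NULL),
                   class = "beam_solution")
  st <- extract_beam_strains(sol)
  expect_equal(abs(st$eps_b), 2 * sec$r * chi, tolerance = 1e-12)
  expect_equal(st$eps_a, 0, tolerance = 1e-12)
  expect_false(st$K_usable)
  # adding a uniform axial strain leaves eps_b unchanged
  sol$u[, 2] <- 0.001 * c(0, 0.5, 1)
  st2 <- extract_beam_strains(sol)
  expect_equal(st2$eps_b, st$eps_b, tolerance = 1e-12)
  expect_equal(st2$eps_a, 0.001, tolerance = 1e-12)
})

test_that("strain ratio is antisymmetric between mirrored tension/compression", {
  sec <- beam_section(); sup <- beam_support()
  F <- f_target(poroelastic_material())
  for (th in c(pi / 16, 3 * pi / 16, 6 * pi / 16)) {
    a <- extract_beam_strains(solve_beam_static(sec, sup, load_pulse(F, theta = th)))
    b <- extract_beam_strains(solve_beam_static(sec, sup,
                                                load_pulse(F, theta = pi - th)))
    expect_equal(a$eps_a, -b$eps_a, tolerance = 1e-9)
    expect_equal(abs(a$K_eps), abs(b$K_eps), tolerance = 1e-7)
  }
})

test_that("near-horizontal load flags the strain ratio unusable", {
  st <- extract_beam_strains(
    solve_beam_static(beam_section(), beam_support(), load_pulse(0.7, theta = pi / 2)))
  expect_false(st$K_usable)
  expect_true(is.na(st$K_eps))
})
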