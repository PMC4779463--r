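test_that("line fits match the closed-form normal equations", {
  f <- fit_linear(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  # hand set solved by the normal equations
  x <- c(0, 1, 2); y <- c(0, 1, 2.1)
  n <- 3; sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  icept <- (sy - slope * sx) / n
  f2 <- fit_linear(x, y)
  expect_equal(f2$slope, slope, tolerance = 1e-12)
  expect_equal(f2$intercept, icept, tolerance = 1e-12)
  # degenerate cases
  f3 <- fit_linear(x, rep(3, 3))
  expect_equal(f3$slope, 0)
  expect_equal(f3$r2, 0)
  expect_error(fit_linear(rep(1, 3), y), "variance")
})

test_that("the cubic reorientation law is recovered from its own data", {
  a <- -0.1129; b <- 0.6725
  K <- seq(-1.4, 1.4, length.out = 15)
  dphi <- a * K^3 + b * K
  fit <- fit_reorientation_law(K, dphi)
  expect_equal(fit$a, a, tolerance = 1e-10)
  expect_equal(fit$b, b, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # the full cubic on antisymmetric data has vanishing even coefficients
  expect_equal(fit$P[c(1, 3)], c(0, 0), tolerance = 1e-10)
  expect_error(fit_reorientation_law(K[1], dphi[1]), ">= 2")
})

test_that("the odd-only law is exactly antisymmetric and zero at zero", {
  set.seed(3)
  K <- runif(12, -2, 2)
  fit <- fit_reorientation_law(K, 0.5 * K + rnorm(12, sd = 0.05))
  pred <- function(x) fit$a * x^3 + fit$b * x
  x <- seq(0.1, 2, by = 0.3)
  expect_equal(pred(-x), -pred(x), tolerance = 1e-12)
  expect_equal(pred(0), 0)
})

test_that("the section law recovers printed-style coefficients exactly", {
  i0 <- -274.654; j0 <- 999.7622; k0 <- -0.065
  thetas <- c(1, 2, 3, 5, 6, 10, 11, 13, 14, 15) * pi / 16
  recs <- do.call(rbind, lapply(thetas, function(th) {
    K <- 0.9 * sin(2 * th)          # any smooth antisymmetric map
    sgn <- ifelse(th < pi / 2, 1, -1)
    eps <- sgn * 1.25e-3 * c(0.5, 1, 2)
    data.frame(theta = th, eps_a = eps, K_eps = K,
               R_A = (i0 * K + sign(eps) * j0) * eps + k0)
  }))
  sec <- fit_section_law(recs)
  expect_equal(sec$i, i0, tolerance = 1e-9)
  expect_equal(sec$j, j0, tolerance = 1e-9)
  expect_equal(sec$k_mean, k0, tolerance = 1e-12)
  expect_equal(sec$tension$r2, 1, tolerance = 1e-12)
  expect_equal(sec$compression$r2, 1, tolerance = 1e-12)
  # tension and compression slope laws differ only by the sign of j
  expect_equal(sec$tension$slope, sec$compression$slope, tolerance = 1e-9)
  expect_equal(sec$tension$intercept, -sec$compression$intercept,
               tolerance = 1e-9)
  # constant per-angle intercepts pool to k_mean = c
  expect_equal(mean(sec$angle_fits$intercept), k0, tolerance = 1e-12)
  expect_error(fit_section_law(recs[recs$theta < pi / 2, ]), "compression")
})

test_that("forward prediction evaluates the printed laws", {
  law <- phenom_law(list(a = -0.1129, b = 0.6725, P = NULL, r2 = 1,
                         r2_full = 1),
                    list(i = -274.654, j = 999.7622, k_mean = -0.065,
                         angle_fits = NULL, tension = NULL,
                         compression = NULL))
  p1 <- predict_adaptation(1.25e-3, K_eps = 0, law)
  expect_equal(p1$dphi, 0)
  expect_equal(p1$R_A, 999.7622 * 1.25e-3 - 0.065, tolerance = 1e-12)
  expect_equal(p1$R_A, 1.1847, tolerance = 1e-4)
  p2 <- predict_adaptation(1e-3, K_eps = 1, law)
  expect_equal(p2$dphi, -0.1129 + 0.6725, tolerance = 1e-12)
  expect_equal(p2$dphi, 0.5596, tolerance = 1e-12)
  # undefined sign at zero axial strain
  p3 <- predict_adaptation(0, K_eps = 0.5, law)
  expect_true(is.na(p3$R_A))
  expect_false(is.na(p3$dphi))
  # broom-style accessors
  td <- tidy(law)
  expect_equal(td$estimate[td$term == "b"], 0.6725)
})
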