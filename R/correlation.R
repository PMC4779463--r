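#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors (at least 3 points)
#' @return list with `slope`, `intercept`, `r2`
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero variance in x: line fit is undefined")
  fit <- stats::lm(y ~ x)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r_squared(y, stats::fitted(fit)))
}

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(0)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Fit the reorientation law
#'
#' Least-squares cubic relating the beam reorientation to the bending-to-
#' axial strain ratio. With `odd_only = TRUE` (the adopted law form) the
#' basis is restricted to \{x, x^3\}, making the law exactly antisymmetric;
#' the full cubic is retained for diagnostics.
#'
#' @param K_eps strain ratio values
#' @param dphi reorientation values (rad)
#' @param odd_only restrict the basis to odd powers
#' @return list with coefficients `a` (cubic), `b` (linear), the full cubic
#'   coefficients `P` (intercept, x, x^2, x^3), and `r2` / `r2_full`
#' @export
fit_reorientation_law <- function(K_eps, dphi, odd_only = TRUE) {
  ok <- is.finite(K_eps) & is.finite(dphi)
  K_eps <- K_eps[ok]; dphi <- dphi[ok]
  if (odd_only && length(K_eps) < 2) stop("odd-only cubic fit needs >= 2 points")
  if (length(K_eps) < 4) {
    if (!odd_only) stop("full cubic fit needs >= 4 points")
    P <- rep(NA_real_, 4); r2f <- NA_real_
  }
  X <- cbind(K_eps^3, K_eps)
  cf <- stats::lm.fit(X, dphi)$coefficients
  yhat <- X %*% cf
  r2 <- r_squared(dphi, yhat)
  if (length(K_eps) >= 4) {
    full <- stats::lm(dphi ~ K_eps + I(K_eps^2) + I(K_eps^3))
    P <- unname(coef(full))
    r2f <- r_squared(dphi, stats::fitted(full))
  }
  list(a = unname(cf[1]), b = unname(cf[2]), P = P,
       r2 = if (odd_only) r2 else r2f, r2_odd = r2, r2_full = r2f)
}

#' Fit the cross-section law
#'
#' Per-angle ordinary least-squares fits of the cross-section ratio against
#' the axial strain across load amplitudes; the per-angle slopes are then
#' regressed linearly on the strain ratio separately in the tension
#' (theta < pi/2) and compression (theta > pi/2) subdomains (the slope law
#' h = i K + sign(eps_a) j), excluding the discontinuity point K = 0; the
#' intercept k_mean is the mean of the per-angle intercepts.
#'
#' @param records data frame with columns `theta`, `eps_a`, `K_eps`, `R_A`
#' @return list with `angle_fits` (tibble: theta, K_eps, slope, intercept,
#'   r2, n), `i`, `j`, `k_mean`, subdomain fits `tension`/`compression`
#'   (slope, intercept, r2)
#' @export
fit_section_law <- function(records) {
  stopifnot(all(c("theta", "eps_a", "K_eps", "R_A") %in% names(records)))
  angle_fits <- records |>
    dplyr::group_by(.data$theta) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::summarise(
      K_eps = mean(.data$K_eps),
      fit = list(fit_linear(.data$eps_a, .data$R_A)),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(slope = purrr::map_dbl(.data$fit, "slope"),
                  intercept = purrr::map_dbl(.data$fit, "intercept"),
                  r2 = purrr::map_dbl(.data$fit, "r2")) |>
    dplyr::select(-"fit")
  if (!nrow(angle_fits)) stop("no angle group spans >= 3 amplitudes")
  k_mean <- mean(angle_fits$intercept)
  sub <- function(sel, label) {
    d <- angle_fits[sel & abs(angle_fits$K_eps) > 1e-9, ]
    if (nrow(d) < 2) stop("subdomain '", label, "' has fewer than 2 angles")
    f <- stats::lm(slope ~ K_eps, data = d)
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         r2 = r_squared(d$slope, stats::fitted(f)), n = nrow(d))
  }
  tension <- sub(angle_fits$theta < pi / 2, "tension")
  compression <- sub(angle_fits$theta > pi / 2, "compression")
  # h(eps_a, K) = i K + sign(eps_a) j: tension slope = i K + j,
  # compression slope = i K - j
  i_coef <- (tension$slope + compression$slope) / 2
  j_coef <- (tension$intercept - compression$intercept) / 2
  list(angle_fits = angle_fits, i = i_coef, j = j_coef, k_mean = k_mean,
       tension = tension, compression = compression)
}

#' Assemble a phenomenological adaptation law
#'
#' Combines the fitted reorientation law (dphi = a K^3 + b K) and
#' cross-section law (R_A = (i K + sign(eps_a) j) eps_a + k_mean) into one
#' object. Strains are dimensionless (e.g. 1.25e-3), which makes j of order
#' 1000.
#'
#' @param reorientation output of [fit_reorientation_law()]
#' @param section output of [fit_section_law()]
#' @return an object of class `phenom_law`
#' @export
phenom_law <- function(reorientation, section) {
  structure(list(a = reorientation$a, b = reorientation$b,
                 i = section$i, j = section$j, k_mean = section$k_mean,
                 reorientation = reorientation, section = section),
            class = "phenom_law")
}

#' Predict adaptation from beam strains
#'
#' Forward evaluation of the fitted laws: reorientation from the strain
#' ratio, cross-section ratio from the axial strain and strain ratio. With
#' `eps_a = 0` the sign in the cross-section law is undefined and `R_A` is
#' returned as NA.
#'
#' @param eps_a axial strain at the central axis (dimensionless)
#' @param K_eps bending-to-axial strain ratio
#' @param law a `phenom_law`
#' @return tibble with columns `dphi` (rad) and `R_A`
#' @export
predict_adaptation <- function(eps_a, K_eps, law) {
  dphi <- law$a * K_eps^3 + law$b * K_eps
  R_A <- ifelse(eps_a == 0, NA_real_,
                (law$i * K_eps + sign(eps_a) * law$j) * eps_a + law$k_mean)
  tibble::tibble(dphi = dphi, R_A = R_A)
}

#' @export
print.phenom_law <- function(x, ...) {
  cat("Phenomenological adaptation laws\n")
  cat(sprintf("  dphi = %.4g K^3 + %.4g K   (R2 = %.4f)\n",
              x$a, x$b, x$reorientation$r2))
  cat(sprintf("  R_A  = (%.4g K + sign(eps_a) %.4g) eps_a + %.4g\n",
              x$i, x$j, x$k_mean))
  invisible(x)
}

#' @method tidy phenom_law
#' @export
tidy.phenom_law <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "i", "j", "k_mean"),
                 estimate = c(x$a, x$b, x$i, x$j, x$k_mean))
}

#' @method glance phenom_law
#' @export
glance.phenom_law <- function(x, ...) {
  tibble::tibble(r2_reorientation = x$reorientation$r2,
                 r2_full_cubic = x$reorientation$r2_full,
                 r2_tension_slope = x$section$tension$r2,
                 r2_compression_slope = x$section$compression$r2,
                 min_r2_angle = min(x$section$angle_fits$r2),
                 n_angles = nrow(x$section$angle_fits))
}

#' @method autoplot phenom_law
#' @export
autoplot.phenom_law <- function(object, K_range = c(-1.5, 1.5), ...) {
  K <- seq(K_range[1], K_range[2], length.out = 200)
  df <- tibble::tibble(K_eps = K, dphi = object$a * K^3 + object$b * K)
  ggplot2::ggplot(df, ggplot2::aes(.data$K_eps, .data$dphi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(K[epsilon]),
                  y = expression(Delta * varphi ~ "(rad)"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
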