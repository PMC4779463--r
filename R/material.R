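#' Poroelastic material description
#'
#' Bundles the drained elastic constants of the bone matrix with the fluid and
#' solid compressibilities, porosity, intrinsic permeability and fluid
#' viscosity that define an isotropic linear Biot poroelastic medium. Units are
#' N, mm, s throughout: moduli in N/mm^2, permeability in mm^2, viscosity in
#' N·s/mm^2.
#'
#' Defaults are the trabecular bone constants used throughout the package:
#' drained E = 18000 N/mm^2, nu = 0.3, solid bulk modulus Ks = 20000 N/mm^2,
#' fluid bulk modulus Kf = 2300 N/mm^2, porosity 5 %, permeability 1e-14 mm^2
#' (1e-20 m^2), viscosity 1e-9 N·s/mm^2 (salt-water like), specific weight
#' 9.8e-6 N/mm^3 (unused unless a gravity head is enabled; mechanical loading
#' only by default).
#'
#' @param E drained Young's modulus (N/mm^2)
#' @param nu drained Poisson's ratio
#' @param Ks solid matrix bulk modulus (N/mm^2)
#' @param Kf fluid bulk modulus (N/mm^2)
#' @param phi porosity (pore volume fraction)
#' @param kappa intrinsic permeability (mm^2)
#' @param mu fluid dynamic viscosity (N·s/mm^2)
#' @param gamma_f fluid specific weight (N/mm^3)
#' @return an object of class `poroelastic_material` with the inputs plus the
#'   derived constants `G`, `K`, `alpha` (Biot effective stress coefficient)
#'   and `M` (Biot storage modulus).
#' @export
poroelastic_material <- function(E = 18000, nu = 0.3, Ks = 20000, Kf = 2300,
                                 phi = 0.05, kappa = 1e-14, mu = 1e-9,
                                 gamma_f = 9.8e-6) {
  stopifnot(E > 0, nu > 0, nu < 0.5, Ks > 0, Kf > 0,
            phi > 0, phi < 1, kappa > 0, mu > 0, gamma_f > 0)
  mat <- list(E = E, nu = nu, Ks = Ks, Kf = Kf, phi = phi,
              kappa = kappa, mu = mu, gamma_f = gamma_f)
  mat <- c(mat, derived_coefficients(mat))
  structure(mat, class = "poroelastic_material")
}

#' Derived Biot coefficients
#'
#' Computes the drained shear and bulk moduli from (E, nu), the Biot effective
#' stress coefficient alpha = 1 - K/Ks and the Biot storage modulus M from
#' 1/M = phi/Kf + (alpha - phi)/Ks.
#'
#' @param material a `poroelastic_material` or a bare list with fields
#'   `E, nu, Ks, Kf, phi`
#' @return list with `G`, `K`, `alpha`, `M`
#' @export
derived_coefficients <- function(material) {
  G <- material$E / (2 * (1 + material$nu))
  K <- material$E / (3 * (1 - 2 * material$nu))
  if (K >= material$Ks) {
    stop("drained bulk modulus K >= Ks gives a non-positive Biot coefficient; ",
         "unphysical for this model")
  }
  alpha <- 1 - K / material$Ks
  Minv <- material$phi / material$Kf + (alpha - material$phi) / material$Ks
  stopifnot(Minv > 0)
  list(G = G, K = K, alpha = alpha, M = 1 / Minv)
}

#' @export
print.poroelastic_material <- function(x, ...) {
  cat("Poroelastic material (N, mm, s units)\n")
  cat(sprintf("  E = %g N/mm^2, nu = %g  (G = %.4g, K = %.4g)\n",
              x$E, x$nu, x$G, x$K))
  cat(sprintf("  Ks = %g, Kf = %g, phi = %g  ->  alpha = %.4g, M = %.4g\n",
              x$Ks, x$Kf, x$phi, x$alpha, x$M))
  cat(sprintf("  kappa = %g mm^2, mu = %g N.s/mm^2 (kappa/mu = %g)\n",
              x$kappa, x$mu, x$kappa / x$mu))
  invisible(x)
}

#' Material used by the remodelling pipeline
#'
#' Identical to [poroelastic_material()] except for the interstitial
#' transport coefficient: the permeability is derived from a hydraulic
#' conductivity of 1e-14 mm/s (kappa = conductivity * mu / gamma_f, about
#' 1.02e-18 mm^2, so kappa/mu is about 1.02e-9 mm^4/(N s)).
#'
#' At the nominal intrinsic permeability (1e-14 mm^2) the pore fluid drains
#' almost completely within every 0.1 s load increment; the characteristic
#' surface velocity then scales with the loading rate but is insensitive to
#' the trabecula width, so the surface-remodelling rule has no equilibrium:
#' loads below the dead band thin the section indefinitely and loads above
#' it thicken it indefinitely. With the conductivity-based coefficient the
#' response stays in the partially drained regime, the characteristic
#' velocity falls with increasing width, every load amplitude finds an
#' equilibrium width, and the velocities at the Mechanostat target load are
#' of the same order (1e-8 mm/s) as the published calibrated dead band
#' (4.8e-8 to 5.2e-8 mm/s). See the methods vignette for the full argument.
#'
#' @param conductivity hydraulic conductivity (mm/s)
#' @param ... other arguments passed to [poroelastic_material()]
#' @return a `poroelastic_material`
#' @export
remodelling_material <- function(conductivity = 1e-14, ...) {
  args <- list(...)
  mu <- args$mu %||% 1e-9
  gamma_f <- args$gamma_f %||% 9.8e-6
  do.call(poroelastic_material,
          c(list(kappa = conductivity * mu / gamma_f), args))
}

#' Load pulse description
#'
#' A load of amplitude `F` applied at angle `theta` from the vertical axis
#' (anticlockwise positive; theta = 0 pulls vertically upward, i.e. tension,
#' theta = pi pushes downward, compression). Transient analyses discretise
#' `total_time` into equal increments and scale the amplitude by a time
#' profile: `"triangular"` ramps linearly to F over the first half of the step
#' and back to zero over the second half; `"ramp"` ramps linearly from
#' zero to F over the whole step; `"step"` applies F from the first increment.
#'
#' @param F load amplitude (N)
#' @param theta load angle to the vertical (rad), in `[0, pi]` for the study
#'   plan; arbitrary angles are accepted
#' @param total_time transient step duration (s)
#' @param increment time increment (s); must divide `total_time`
#' @param profile one of "triangular", "ramp", "step"
#' @return an object of class `load_pulse`
#' @export
load_pulse <- function(F, theta = 0, total_time = 1, increment = 0.1,
                       profile = c("triangular", "ramp", "step")) {
  profile <- match.arg(profile)
  stopifnot(F >= 0, total_time > 0, increment > 0)
  nstep <- total_time / increment
  if (abs(nstep - round(nstep)) > 1e-9) {
    stop("increment must divide total_time")
  }
  structure(list(F = F, theta = theta, total_time = total_time,
                 increment = increment, nstep = as.integer(round(nstep)),
                 profile = profile),
            class = "load_pulse")
}

#' Load scale factors at increment endpoints
#'
#' @param pulse a `load_pulse`
#' @return numeric vector of length `nstep`, the fraction of the amplitude
#'   applied at the end of each increment
#' @export
pulse_profile <- function(pulse) {
  t <- seq_len(pulse$nstep) * pulse$increment
  T <- pulse$total_time
  switch(pulse$profile,
         triangular = ifelse(t <= T / 2, 2 * t / T, 2 * (T - t) / T),
         ramp = t / T,
         step = rep(1, length(t)))
}

#' Unit load direction vector
#'
#' @param theta angle to the vertical axis (rad)
#' @return length-2 unit vector (x1, x2); theta = 0 is (0, 1)
#' @export
load_direction <- function(theta) c(sin(theta), cos(theta))
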