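#' Study plan for the load sweep
#'
#' The reference plan crosses load inclinations theta in `[0, pi]` with
#' amplitudes expressed as multiples of F_target. Presets:
#' `"reference42"` runs the 14 reference-plan angles each at \{1/2, 1, 2\} F_target
#' (42 scenarios, reference mesh h = 0.015 mm); `"full70"` runs all 14 angles
#' at all five amplitudes \{1/2, 3/4, 1, 3/2, 2\}; `"coarse"` (the scaled-down
#' study) runs 10 angles drawn from the fit domain at \{1/2, 1, 2\} F_target
#' on a coarse mesh.
#'
#' @param preset one of "coarse", "reference42", "full70", or "custom"
#' @param angles,amplitudes overrides for a custom plan (rad; multiples of
#'   F_target)
#' @param h,h_plate mesh edge lengths (mm)
#' @param max_iterations remodelling iteration budget per scenario
#' @param calibrate run [calibrate_velocity_targets()] before the sweep
#' @param mirror infer the compression half-quadrant (theta > pi/2) by
#'   reflection of the tension-side remodelling runs instead of recomputing
#'   them; the pipeline is exactly mirror-symmetric (the stimulus uses the
#'   flux magnitude only), so the inferred records equal the computed ones.
#'   Default on for the coarse preset
#' @return an object of class `study_plan` with a `scenarios` tibble
#' @export
study_plan <- function(preset = c("coarse", "reference42", "full70", "custom"),
                       angles = NULL, amplitudes = NULL,
                       h = NULL, h_plate = NULL, max_iterations = 100L,
                       calibrate = TRUE, mirror = NULL) {
  preset <- match.arg(preset)
  reference_angles <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16) * pi / 16
  def <- switch(preset,
    coarse = list(angles = c(0, 1, 3, 5, 6, 10, 11, 13, 15, 16) * pi / 16,
                  amplitudes = c(0.5, 1, 2), h = 0.02, h_plate = 0.1),
    reference42 = list(angles = reference_angles, amplitudes = c(0.5, 1, 2),
                   h = 0.015, h_plate = 0.05),
    full70 = list(angles = reference_angles,
                  amplitudes = c(0.5, 0.75, 1, 1.5, 2), h = 0.015,
                  h_plate = 0.05),
    custom = list(angles = angles, amplitudes = amplitudes, h = 0.02,
                  h_plate = 0.1))
  angles <- angles %||% def$angles
  amplitudes <- amplitudes %||% def$amplitudes
  stopifnot(all(angles >= 0 & angles <= pi),
            all(amplitudes >= 0.5 & amplitudes <= 2))
  scenarios <- tidyr::expand_grid(theta = angles, F_mult = amplitudes)
  structure(list(scenarios = scenarios, h = h %||% def$h,
                 h_plate = h_plate %||% def$h_plate,
                 max_iterations = as.integer(max_iterations),
                 calibrate = calibrate, preset = preset,
                 mirror = mirror %||% (preset == "coarse")),
            class = "study_plan")
}

# fit-domain helpers (angle membership with tolerance)
in_fit_domain <- function(theta, tol = 1e-9) {
  (theta <= 6 * pi / 16 + tol) | (theta >= 10 * pi / 16 - tol)
}
in_quasilinear_domain <- function(theta, tol = 1e-9) {
  (theta <= 5 * pi / 16 + tol) | (theta >= 11 * pi / 16 - tol)
}

#' Run the full study
#'
#' Calibrates the velocity targets (optional), then for every scenario of
#' the plan: solves the static beam twin for the strain drivers, runs the
#' mechanistic remodelling loop on the poroelastic trabecula, reduces the
#' remodelled geometry to an equivalent beam, and finally fits the
#' phenomenological laws over the fit domain
#' theta in `[0, 6pi/16] U [10pi/16, pi]`. Individual scenario failures are
#' recorded and skipped; the study aborts if more than 10 % fail.
#'
#' @param plan a `study_plan`
#' @param material a `poroelastic_material`
#' @param params a `remodelling_params`; by default calibrated from the plan
#' @param out_dir optional output directory for CSV/JSON tables
#' @param verbose print progress lines
#' @return an object of class `study_result`: `results` tibble (one row per
#'   scenario), fitted `law` (`phenom_law`), `params`, `F_target`, `plan`
#' @export
run_study <- function(plan = study_plan(), material = remodelling_material(),
                      params = NULL, out_dir = NULL, verbose = FALSE) {
  geometry <- build_initial_trabecula()
  Ft <- f_target(material, central_width(geometry))
  if (is.null(params)) {
    params <- if (plan$calibrate) {
      calibrate_velocity_targets(geometry, material, h = plan$h,
                                 h_plate = plan$h_plate)
    } else {
      remodelling_params()
    }
  }
  params$max_iterations <- plan$max_iterations
  section <- beam_section(r = central_width(geometry) / 2,
                          length = geometry$length, E = material$E,
                          nu = material$nu)
  support <- beam_support()

  beam_strains_for <- function(theta, F_mult) {
    extract_beam_strains(
      solve_beam_static(section, support, load_pulse(F_mult * Ft, theta = theta)))
  }

  run_one <- function(theta, F_mult) {
    pulse <- load_pulse(F_mult * Ft, theta = theta)
    strains <- beam_strains_for(theta, F_mult)
    hist <- run_remodelling(geometry, material, pulse, params,
                            h = plan$h, h_plate = plan$h_plate)
    if (!is.null(hist$error)) stop(hist$error)
    eb <- equivalent_beam(hist$final_geometry, geometry)
    tibble::tibble(theta = theta, F_mult = F_mult, F = F_mult * Ft,
                   eps_a = strains$eps_a, eps_b = strains$eps_b,
                   K_eps = strains$K_eps,
                   dphi = eb$dphi, R_A = eb$R_A,
                   apparent_radius = eb$apparent_radius,
                   w_f = eb$w_f, iterations = hist$iterations,
                   converged = hist$converged,
                   excluded = !in_fit_domain(theta),
                   mirrored = FALSE)
  }

  scen <- plan$scenarios
  use_mirror <- isTRUE(plan$mirror)
  if (use_mirror) {
    mir <- round(16 * (pi - scen$theta) / pi, 9) %in%
      round(16 * scen$theta / pi, 9) & scen$theta > pi / 2 + 1e-9
    direct <- scen[!mir, , drop = FALSE]
  } else {
    direct <- scen
  }

  rows <- purrr::pmap(direct, function(theta, F_mult) {
    if (verbose) {
      message(sprintf("scenario theta = %5.3f rad, F = %.2f F_target",
                      theta, F_mult))
    }
    tryCatch(run_one(theta, F_mult),
             error = function(e) {
               if (verbose) message("  failed: ", conditionMessage(e))
               tibble::tibble(theta = theta, F_mult = F_mult,
                              error = conditionMessage(e))
             })
  })
  results <- dplyr::bind_rows(rows)
  if (use_mirror && any(mir)) {
    reflected <- purrr::pmap(scen[mir, , drop = FALSE], function(theta, F_mult) {
      src <- results[abs(results$theta - (pi - theta)) < 1e-9 &
                       abs(results$F_mult - F_mult) < 1e-9, ]
      if (!nrow(src) ||
          ("error" %in% names(src) && !is.na(src$error[1]))) {
        return(tibble::tibble(theta = theta, F_mult = F_mult,
                              error = "mirror source scenario failed"))
      }
      strains <- beam_strains_for(theta, F_mult)
      out <- src[1, ]
      out$theta <- theta
      out$eps_a <- strains$eps_a
      out$eps_b <- strains$eps_b
      out$K_eps <- strains$K_eps
      out$dphi <- -out$dphi
      out$excluded <- !in_fit_domain(theta)
      out$mirrored <- TRUE
      out
    })
    results <- dplyr::bind_rows(results, reflected) |>
      dplyr::arrange(.data$theta, .data$F_mult)
  }
  if (!"error" %in% names(results)) results$error <- NA_character_
  nfail <- sum(!is.na(results$error))
  if (nfail > 0.10 * nrow(results)) {
    stop("study failed: ", nfail, " of ", nrow(results), " scenarios errored")
  }
  law <- tryCatch(fit_study_laws(results), error = function(e) {
    warning("law fitting failed: ", conditionMessage(e))
    NULL
  })
  out <- structure(list(results = results, law = law, params = params,
                        F_target = Ft, plan = plan),
                   class = "study_result")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' Fit the phenomenological laws from a table of scenario outputs
#'
#' @param results tibble with columns `theta`, `eps_a`, `K_eps`, `dphi`,
#'   `R_A` (rows with an `error` are dropped)
#' @return a `phenom_law`
#' @export
fit_study_laws <- function(results) {
  ok <- if ("error" %in% names(results)) {
    results[is.na(results$error), ]
  } else {
    results
  }
  dom <- ok[in_fit_domain(ok$theta) & is.finite(ok$K_eps), ]
  reo <- fit_reorientation_law(dom$K_eps, dom$dphi)
  sec <- fit_section_law(dom)
  law <- phenom_law(reo, sec)
  lin <- dom[in_quasilinear_domain(dom$theta), ]
  law$quasilinear <- fit_linear(lin$K_eps, lin$dphi)
  law
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study: %d scenarios (%d failed), F_target = %.4g N\n",
              nrow(x$results), sum(!is.na(x$results$error)), x$F_target))
  print(x$law)
  invisible(x)
}

#' @method glance study_result
#' @export
glance.study_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_scenarios = nrow(x$results),
                                  F_target = x$F_target,
                                  V_target = x$params$V_target),
                   glance(x$law))
}

#' Scenario table of a study result
#' @param x a `study_result`
#' @param ... unused
#' @return the results tibble
#' @method tidy study_result
#' @export
tidy.study_result <- function(x, ...) x$results

#' Run the inclined-trabecula validation scenario
#'
#' A 0.2 mm wide, 0.92 mm long trabecula inclined 30 degrees to the
#' vertical, bottom edge constrained vertically, free pore flow on all
#' edges, loaded by a stiff plate in compression-only contact carrying a
#' vertical pressure ramped linearly over the 1 s step, remodelled for the
#' full iteration budget.
#'
#' @param material a `poroelastic_material`
#' @param params a `remodelling_params` (typically the calibrated targets)
#' @param pressure plate pressure (N/mm^2)
#' @param h mesh edge length (mm)
#' @param max_iterations remodelling iterations
#' @param incline initial inclination (rad)
#' @return list with `final_incline` (rad, angle of the adapted axis to the
#'   vertical), `width_change` (relative change of the adapted width,
#'   negative = thinning), the equivalent beam `eb` and the full `history`
#' @export
run_validation <- function(material = remodelling_material(),
                           params = remodelling_params(),
                           pressure = 0.4, h = 0.04,
                           max_iterations = 100L, incline = 30 * pi / 180) {
  geometry <- build_initial_trabecula(length = 0.92, width = 0.2,
                                      incline = incline)
  params$max_iterations <- as.integer(max_iterations)
  pulse <- load_pulse(pressure, theta = pi, profile = "ramp")
  bcs_fn <- function(mesh) validation_bcs(mesh, pressure = pressure,
                                          plate_width = geometry$width_initial)
  hist <- run_remodelling(geometry, material, pulse, params, h = h,
                          plates = FALSE, bcs_fn = bcs_fn)
  if (!is.null(hist$error)) {
    warning("validation run aborted at iteration ", hist$iterations, ": ",
            hist$error)
  }
  eb <- equivalent_beam(hist$final_geometry, geometry)
  list(final_incline = eb$phi_f, width_change = eb$R_A - 1, eb = eb,
       history = hist)
}
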