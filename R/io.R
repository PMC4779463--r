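#' Write study outputs to a directory
#'
#' Writes `equivalent_beams.csv` (per-scenario records), `fits.csv`
#' (per-angle line fits), `laws.json` (fitted law coefficients, fit
#' R-squared values, fit domains and the strain-unit declaration) and
#' `manifest.json` (plan, material-independent run parameters).
#'
#' @param study a `study_result`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$results, file.path(dir, "equivalent_beams.csv"),
                   row.names = FALSE)
  utils::write.csv(study$law$section$angle_fits, file.path(dir, "fits.csv"),
                   row.names = FALSE)
  law <- study$law
  jsonlite::write_json(list(
    a = law$a, b = law$b, i = law$i, j = law$j, k_mean = law$k_mean,
    r2 = list(reorientation_cubic = law$reorientation$r2,
              reorientation_full_cubic = law$reorientation$r2_full,
              reorientation_linear_restricted = law$quasilinear$r2,
              tension_slope = law$section$tension$r2,
              compression_slope = law$section$compression$r2,
              min_per_angle = min(law$section$angle_fits$r2)),
    fit_domain = "theta in [0, 6pi/16] U [10pi/16, pi]",
    quasilinear_domain = "theta in [0, 5pi/16] U [11pi/16, pi]",
    strain_unit = "dimensionless strain",
    k_mean_pooling = "mean of per-angle intercepts over the full fit domain"),
    file.path(dir, "laws.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    preset = study$plan$preset,
    h = study$plan$h, h_plate = study$plan$h_plate,
    max_iterations = study$plan$max_iterations,
    F_target = study$F_target,
    V_target = study$params$V_target,
    V_apposition = study$params$V_apposition,
    V_resorption = study$params$V_resorption,
    scenarios = nrow(study$results)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a remodelling history's characteristic points to CSV
#'
#' Columns: iteration, side, index, x1, x2, V, displacement.
#'
#' @param history a `remodelling_history`
#' @param file output path
#' @return `file`, invisibly
#' @export
write_history_csv <- function(history, file) {
  rows <- purrr::map_dfr(seq_along(history$geometries), function(i) {
    dplyr::mutate(characteristic_points(history$geometries[[i]]),
                  iteration = i - 1L)
  })
  per_it <- tidy(history)
  if (nrow(per_it)) {
    rows <- dplyr::left_join(rows, per_it,
                             by = c("iteration", "side", "index"))
  } else {
    rows$V <- NA_real_; rows$displacement <- NA_real_
  }
  utils::write.csv(rows[, c("iteration", "side", "index", "x1", "x2",
                            "V", "displacement")], file, row.names = FALSE)
  invisible(file)
}

#' Write a mesh (with optional fields) as a legacy ASCII VTK file
#'
#' Quadrilateral cells with optional nodal point data (e.g. displacement
#' magnitude, pore pressure) and per-element cell data (e.g. flux
#' magnitude).
#'
#' @param mesh an `fe_mesh`
#' @param file output path
#' @param point_data named list of per-node numeric vectors
#' @param cell_data named list of per-element numeric vectors
#' @return `file`, invisibly
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0", "porotrab mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%g %g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elems[, 1] - 1L,
                     mesh$elems[, 2] - 1L, mesh$elems[, 3] - 1L,
                     mesh$elems[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("9", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}
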