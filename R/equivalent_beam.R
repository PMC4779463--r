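#' Reduce a remodelled geometry to an equivalent beam
#'
#' The equivalent beam's start and end nodes are the midpoints of the bottom
#' and top edges of the trabecula (the middle points between the left and
#' right spline extremities); its inclination to the vertical is obtained
#' from the axis vector (sign from the horizontal component, magnitude
#' consistent with the scalar product with the unit vertical vector). The
#' apparent radius is half the mean horizontal separation of the two lateral
#' splines, measured at the heights of the 12 characteristic point pairs;
#' the remodelled radius is its projection onto the direction perpendicular
#' to the beam axis. The adapted width is twice the remodelled radius and
#' the cross-section ratio R_A is taken against the same width measure of
#' the initial geometry.
#'
#' @param final_geometry remodelled `trabecula_geometry`
#' @param initial_geometry initial `trabecula_geometry`
#' @return an object of class `equivalent_beam`: start/end nodes, `phi_i`,
#'   `phi_f`, `dphi`, `apparent_radius`, `remodelled_radius`, `w_i`, `w_f`,
#'   `R_A`
#' @export
equivalent_beam <- function(final_geometry, initial_geometry) {
  fin <- beam_reduction(final_geometry)
  ini <- beam_reduction(initial_geometry)
  if (!is.finite(fin$phi) || !is.finite(ini$phi)) {
    stop("degenerate axis: equivalent beam inclination is undefined")
  }
  w_i <- 2 * ini$remodelled_radius
  w_f <- 2 * fin$remodelled_radius
  structure(list(start_node = fin$start, end_node = fin$end,
                 phi_i = ini$phi, phi_f = fin$phi, dphi = fin$phi - ini$phi,
                 apparent_radius = fin$apparent_radius,
                 remodelled_radius = fin$remodelled_radius,
                 w_i = w_i, w_f = w_f, R_A = w_f / w_i),
            class = "equivalent_beam")
}

# midpoints, signed inclination to vertical, matched-height apparent radius
beam_reduction <- function(geometry) {
  L <- geometry$left_points; R <- geometry$right_points
  start <- (L[1, ] + R[1, ]) / 2
  end <- (L[nrow(L), ] + R[nrow(R), ]) / 2
  axis <- end - start
  nr <- sqrt(sum(axis^2))
  phi <- if (nr > 0) atan2(axis[1], axis[2]) else NaN
  # horizontal spline separation at the 12 pair mean heights
  y <- (L[, 2] + R[, 2]) / 2
  xl <- stats::splinefun(L[, 2], L[, 1], method = "natural")
  xr <- stats::splinefun(R[, 2], R[, 1], method = "natural")
  widths <- xr(y) - xl(y)
  apparent <- mean(widths) / 2
  list(start = start, end = end, phi = phi, apparent_radius = apparent,
       remodelled_radius = apparent * cos(phi))
}

#' @export
print.equivalent_beam <- function(x, ...) {
  cat(sprintf("Equivalent beam: dphi = %.4g rad (%.2f deg), R_A = %.4g\n",
              x$dphi, x$dphi * 180 / pi, x$R_A))
  invisible(x)
}

#' @method tidy equivalent_beam
#' @export
tidy.equivalent_beam <- function(x, ...) {
  tibble::tibble(phi_i = x$phi_i, phi_f = x$phi_f, dphi = x$dphi,
                 apparent_radius = x$apparent_radius,
                 remodelled_radius = x$remodelled_radius,
                 w_i = x$w_i, w_f = x$w_f, R_A = x$R_A)
}
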