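#' Spline-bounded trabecula geometry
#'
#' A single trabecula is represented as a closed planar region bounded by two
#' interpolating cubic splines (the lateral surfaces, each passing through 12
#' characteristic points ordered bottom to top, extended to the fixed end-edge
#' heights) and two straight end edges joining the sides. Elastic end plates
#' (0.5 mm thick, 1.4 mm wide, 1 mm deep out-of-plane by default) are attached
#' at both ends. Coordinates: origin at the centre of the bottom
#' trabecula-plate junction, x1 horizontal, x2 vertical upward; inclinations
#' are measured from the vertical axis, positive anticlockwise.
#'
#' @name trabecula_geometry
NULL

N_POINTS_SIDE <- 12L

default_plates <- function() list(t = 0.5, w = 1.4, d = 1.0)

new_trabecula_geometry <- function(left_points, right_points, plates,
                                   width_initial, length, incline,
                                   left_span = NULL, right_span = NULL) {
  structure(list(left_points = left_points, right_points = right_points,
                 plates = plates, width_initial = width_initial,
                 length = length, incline = incline,
                 left_span = left_span %||% range(left_points[, 2]),
                 right_span = right_span %||% range(right_points[, 2])),
            class = "trabecula_geometry")
}

#' Build the initial rectangular trabecula
#'
#' The initial trabecula is a rectangle (a cylinder projected on the 2D
#' plane), by default 1 mm long and 0.2 mm wide, with 12 characteristic
#' points uniformly distributed along each lateral side: the side is split
#' into 12 equal cells and the points sit at the cell midpoints (spacing
#' L/12, first point L/24 from the end). Keeping the points off the plate
#' junction corners matters: the corner of the drained lateral edge and the
#' no-flow junction carries a flux singularity whose sampled value does not
#' converge under mesh refinement. A non-zero `incline` rotates the
#' rectangle about the centre of its bottom edge, which stays at the origin.
#'
#' @param length trabecula length (mm)
#' @param width trabecula width (mm)
#' @param incline inclination of the trabecula axis to the vertical (rad),
#'   absolute value below pi/2
#' @param plates list with plate thickness `t`, width `w` and out-of-plane
#'   depth `d` (mm)
#' @return a `trabecula_geometry`
#' @examples
#' g <- build_initial_trabecula()
#' central_width(g)
#' @export
build_initial_trabecula <- function(length = 1, width = 0.2, incline = 0,
                                    plates = default_plates()) {
  if (length <= 0 || width <= 0) stop("invalid geometry: non-positive dimensions")
  if (abs(incline) >= pi / 2) stop("invalid geometry: |incline| must be < pi/2")
  a <- c(sin(incline), cos(incline))    # axis direction
  n <- c(cos(incline), -sin(incline))   # cross-axis direction (to the right)
  s <- (seq_len(N_POINTS_SIDE) - 0.5) / N_POINTS_SIDE
  left <- cbind(-width / 2 * n[1] + s * length * a[1],
                -width / 2 * n[2] + s * length * a[2])
  right <- cbind(width / 2 * n[1] + s * length * a[1],
                 width / 2 * n[2] + s * length * a[2])
  corner_y <- function(sgn) c(sgn * width / 2 * n[2],
                              sgn * width / 2 * n[2] + length * a[2])
  new_trabecula_geometry(left, right, plates, width, length, incline,
                         left_span = corner_y(-1), right_span = corner_y(1))
}

#' Rebuild a geometry from updated characteristic points
#'
#' The lateral boundaries are natural cubic splines through the 12 updated
#' points of each side; the closure is two straight lines joining the top
#' points and the bottom points of the splines. The region must remain simple
#' with strictly positive local width everywhere, otherwise the remodelling
#' run is aborted with a degenerate-geometry error.
#'
#' @param left_points,right_points 12 x 2 matrices of planar coordinates (mm),
#'   ordered bottom to top
#' @param plates plate dimension list (see [build_initial_trabecula()])
#' @param width_initial the reference (initial) width used for ratios (mm)
#' @param incline nominal inclination carried over for bookkeeping (rad)
#' @param left_span,right_span height range (x2) of each lateral side at the
#'   end edges; defaults to the point heights (the remodelling loop carries
#'   the spans of the previous geometry, which never change)
#' @return a `trabecula_geometry`
#' @export
geometry_from_points <- function(left_points, right_points,
                                 plates = default_plates(),
                                 width_initial = NULL, incline = 0,
                                 left_span = NULL, right_span = NULL) {
  left_points <- as.matrix(left_points); right_points <- as.matrix(right_points)
  if (nrow(left_points) != N_POINTS_SIDE || nrow(right_points) != N_POINTS_SIDE) {
    stop("degenerate geometry: each side needs exactly 12 characteristic points")
  }
  len <- sum(sqrt(rowSums(diff((left_points + right_points) / 2)^2)))
  g <- new_trabecula_geometry(left_points, right_points, plates,
                              width_initial %||% NA_real_, len, incline,
                              left_span = left_span, right_span = right_span)
  wmin <- min(side_gap_samples(g))
  if (!is.finite(wmin) || wmin <= 0) {
    stop("degenerate geometry: non-positive local width between the lateral splines")
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chord-length parameterised natural-spline functions for one side;
# returns list(fx(t), fy(t), arc_len) with t in [0, 1]
side_spline <- function(pts) {
  d <- sqrt(rowSums(diff(pts)^2))
  t <- c(0, cumsum(d)) / sum(d)
  list(fx = stats::splinefun(t, pts[, 1], method = "natural"),
       fy = stats::splinefun(t, pts[, 2], method = "natural"),
       arc_len = sum(d), t = t)
}

# signed horizontal separation of the two sides sampled at matched height
# fractions (degeneracy check: crossing surfaces turn it negative)
side_gap_samples <- function(geometry, n = 60) {
  s <- seq(0, 1, length.out = n)
  at <- function(pts, span) {
    stats::splinefun(pts[, 2], pts[, 1],
                     method = "natural")(span[1] + s * diff(span))
  }
  at(geometry$right_points, geometry$right_span) -
    at(geometry$left_points, geometry$left_span)
}

#' Central width of a trabecula geometry
#'
#' The width is approximated as the difference in horizontal position at the
#' middle characteristic points; with 12 points per side the mean of pairs 6
#' and 7 is used as an unbiased centre estimate.
#'
#' @param geometry a `trabecula_geometry`
#' @return central width (mm)
#' @export
central_width <- function(geometry) {
  dx <- geometry$right_points[, 1] - geometry$left_points[, 1]
  mean(dx[c(6L, 7L)])
}

#' Characteristic point spacing along a side
#'
#' Mean spacing of the 12 characteristic points along the lateral boundary
#' (the point-chain arc length divided by 11; L/12 on the initial rectangle),
#' used to size the sphere of influence.
#'
#' @param geometry a `trabecula_geometry`
#' @return named vector with left/right spacings (mm)
#' @export
point_spacing <- function(geometry) {
  c(left = side_spline(geometry$left_points)$arc_len / (N_POINTS_SIDE - 1),
    right = side_spline(geometry$right_points)$arc_len / (N_POINTS_SIDE - 1))
}

#' Characteristic points as a tibble
#'
#' @param geometry a `trabecula_geometry`
#' @return tibble with columns `side`, `index`, `x1`, `x2`
#' @export
characteristic_points <- function(geometry) {
  tibble::tibble(
    side = rep(c("left", "right"), each = N_POINTS_SIDE),
    index = rep(seq_len(N_POINTS_SIDE), 2L),
    x1 = c(geometry$left_points[, 1], geometry$right_points[, 1]),
    x2 = c(geometry$left_points[, 2], geometry$right_points[, 2]))
}

#' @export
print.trabecula_geometry <- function(x, ...) {
  cat(sprintf("Trabecula geometry: %d points/side, central width %.4g mm\n",
              N_POINTS_SIDE, central_width(x)))
  invisible(x)
}

#' @method autoplot trabecula_geometry
#' @export
autoplot.trabecula_geometry <- function(object, ...) {
  sl <- side_spline(object$left_points)
  sr <- side_spline(object$right_points)
  t <- seq(0, 1, length.out = 100)
  outline <- tibble::tibble(
    x1 = c(sl$fx(t), rev(sr$fx(t)), sl$fx(0)),
    x2 = c(sl$fy(t), rev(sr$fy(t)), sl$fy(0)))
  ggplot2::ggplot(outline, ggplot2::aes(.data$x1, .data$x2)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = characteristic_points(object), size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x1 (mm)", y = "x2 (mm)")
}
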