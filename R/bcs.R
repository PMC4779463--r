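#' Boundary conditions for the standard trabecula-with-plates set-up
#'
#' Bottom edge of the bottom plate fixed; all top-plate nodes constrained to
#' translate only along the load direction; pore pressure zero on the
#' trabecula lateral edges (free flow), no-flow at the plate junctions
#' (natural condition); the load applied evenly to the nodes of the top edge
#' of the top plate.
#'
#' @param mesh an `fe_mesh` built with plates
#' @param pulse a `load_pulse` (supplies amplitude and direction)
#' @return a boundary-condition list consumed by [solve_transient()]
#' @export
standard_bcs <- function(mesh, pulse) {
  e <- load_direction(pulse$theta)
  top <- mesh$sets$plate_top_outer_edge
  n <- length(top)
  list(fixed_nodes = mesh$sets$plate_bottom_outer_edge,
       fixed_ux_nodes = integer(0), fixed_uy_nodes = integer(0),
       direction_nodes = mesh$sets$plate_top_nodes, direction = e,
       p_zero_nodes = c(mesh$sets$lateral_left, mesh$sets$lateral_right),
       loads = data.frame(node = top, fx = pulse$F * e[1] / n,
                          fy = pulse$F * e[2] / n))
}

#' Boundary conditions for a 1D consolidation column
#'
#' Laterally confined column: horizontal displacement fixed everywhere,
#' vertical displacement fixed at the base, drainage (p = 0) at the top only,
#' and a uniform vertical traction on the top edge (consistent trapezoidal
#' nodal loads).
#'
#' @param mesh an `fe_mesh` from [rect_mesh()]
#' @param sigma0 compressive traction magnitude applied downward on the top
#'   edge (N/mm^2)
#' @return a boundary-condition list
#' @export
column_bcs <- function(mesh, sigma0) {
  top <- mesh$sets$top
  x <- mesh$nodes[top, 1]
  o <- order(x); top <- top[o]; x <- x[o]
  # trapezoidal weights for a uniform edge traction
  wgt <- numeric(length(x))
  dx <- diff(x)
  wgt[-length(x)] <- wgt[-length(x)] + dx / 2
  wgt[-1] <- wgt[-1] + dx / 2
  list(fixed_nodes = integer(0),
       fixed_ux_nodes = mesh$sets$trab_nodes,
       fixed_uy_nodes = mesh$sets$bottom,
       direction_nodes = integer(0), direction = c(0, 1),
       p_zero_nodes = mesh$sets$top,
       loads = data.frame(node = top, fx = 0, fy = -sigma0 * wgt))
}

#' Boundary conditions for the inclined-trabecula validation scenario
#'
#' Bottom edge constrained in the vertical direction (one node also pinned
#' horizontally to remove the rigid mode), free pore flow on all edges, and a
#' stiff plate in compression-only contact with the top edge, loaded by a
#' vertical pressure and free to translate vertically only.
#'
#' @param mesh an `fe_mesh` built without plates
#' @param pressure applied plate pressure (N/mm^2)
#' @param plate_width in-plane width over which the pressure acts (mm); the
#'   resultant on the plate is `pressure * plate_width * depth`
#' @param depth out-of-plane depth (mm)
#' @param penalty contact penalty stiffness (N/mm)
#' @return a boundary-condition list
#' @export
validation_bcs <- function(mesh, pressure = 0.4, plate_width = 0.2,
                           depth = 1, penalty = 1e6) {
  bottom <- mesh$sets$junction_bottom
  top <- mesh$sets$junction_top
  pin <- bottom[which.min(abs(mesh$nodes[bottom, 1] -
                                mean(range(mesh$nodes[bottom, 1]))))]
  boundary <- unique(c(mesh$sets$lateral_left, mesh$sets$lateral_right,
                       bottom, top))
  list(fixed_nodes = integer(0),
       fixed_ux_nodes = pin,
       fixed_uy_nodes = bottom,
       direction_nodes = integer(0), direction = c(0, 1),
       p_zero_nodes = boundary,
       loads = NULL,
       contact = list(nodes = top, plane = max(mesh$nodes[top, 2]),
                      P = pressure * plate_width * depth, penalty = penalty))
}

#' Terzaghi one-dimensional consolidation reference solution
#'
#' Closed-form series solution for the excess pore pressure in a laterally
#' confined poroelastic column of height `column_height`, drained at the top,
#' impermeable at the base, under a step vertical stress. Used as an
#' independent verification oracle for the transient solver.
#'
#' @param column_height column height H (mm)
#' @param material a `poroelastic_material`
#' @param applied_stress magnitude of the compressive step stress (N/mm^2)
#' @param times vector of times (s)
#' @param y heights at which to evaluate (mm, 0 = base, H = drained top);
#'   defaults to 101 equally spaced points
#' @param nterms number of series terms
#' @return list with `p` (length(y) x length(times) matrix of pressures),
#'   `p0` (initial undrained pressure), `c` (consolidation coefficient,
#'   mm^2/s), `y`, `times`
#' @export
terzaghi_reference <- function(column_height, material, applied_stress, times,
                               y = seq(0, column_height, length.out = 101),
                               nterms = 200) {
  H <- column_height
  Kv <- material$K + 4 * material$G / 3
  p0 <- material$alpha * material$M * applied_stress /
    (Kv + material$alpha^2 * material$M)
  cc <- (material$kappa / material$mu) * material$M * Kv /
    (Kv + material$alpha^2 * material$M)
  p <- matrix(0, length(y), length(times))
  for (m in 0:(nterms - 1)) {
    lam <- (2 * m + 1) * pi / (2 * H)
    mode <- sin(lam * (H - y))
    decay <- exp(-lam^2 * cc * times)
    p <- p + (4 * p0 / ((2 * m + 1) * pi)) * outer(mode, decay)
  }
  list(p = p, p0 = p0, c = cc, y = y, times = times)
}
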