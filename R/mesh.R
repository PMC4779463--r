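#' Finite-element meshing of the trabecula and its end plates
#'
#' The spline-bounded trabecula is meshed with a deterministic transfinite
#' (mapped) grid of 4-node quadrilaterals between the two lateral splines;
#' the end plates are structured grids of 4-node quadrilaterals. The
#' trabecula end edges are tied to the plate faces by linear multipoint
#' constraints, so plate and trabecula grids need not match. Meshing the same
#' geometry twice yields the identical mesh.
#'
#' @param geometry a `trabecula_geometry`
#' @param h target element edge length in the trabecula (mm); the default
#'   0.015 mm reproduces the reference discretisation
#' @param h_plate target element edge length in the plates (mm); defaults to
#'   `h`
#' @param plates logical, attach and mesh the end plates (the validation
#'   scenario runs without plates)
#' @param n_across optionally force the number of elements across the width
#' @return an object of class `fe_mesh` with fields `nodes` (n x 2), `elems`
#'   (m x 4 connectivity, counterclockwise), `region` (per-element label),
#'   node `sets`, tie constraints `ties` and tagged boundary `edges`
#' @export
generate_mesh <- function(geometry, h = 0.015, h_plate = NULL, plates = TRUE,
                          n_across = NULL) {
  stopifnot(h > 0)
  h_plate <- h_plate %||% h
  # rule the region at matched height fractions of the two sides: the
  # characteristic points only ever move horizontally, so each lateral
  # boundary is single-valued in x2 and the ruled cells stay valid whenever
  # the local width is positive (robust for strongly reoriented shapes);
  # the side spans reach the end edges, beyond the characteristic points
  level <- function(pts, span, n) {
    y <- seq(span[1], span[2], length.out = n + 1)
    cbind(stats::splinefun(pts[, 2], pts[, 1], method = "natural")(y), y)
  }
  # size the divisions from the sampled boundary: the across count follows
  # the longest ruling so element centroids stay within reach of every
  # characteristic point, the axial count follows the longer side arc
  Ls <- level(geometry$left_points, geometry$left_span, 60)
  Rs <- level(geometry$right_points, geometry$right_span, 60)
  wmax <- max(sqrt((Rs[, 1] - Ls[, 1])^2 + (Rs[, 2] - Ls[, 2])^2))
  arc <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  axis_len <- max(arc(Ls), arc(Rs))
  nx <- n_across %||% max(2L, as.integer(ceiling(wmax / h)))
  ny <- max(4L, as.integer(ceiling(axis_len / h)))

  xi <- seq(0, 1, length.out = nx + 1)
  L <- level(geometry$left_points, geometry$left_span, ny)
  R <- level(geometry$right_points, geometry$right_span, ny)
  X <- outer(xi, R[, 1]) + outer(1 - xi, L[, 1])   # (nx+1) x (ny+1)
  Y <- outer(xi, R[, 2]) + outer(1 - xi, L[, 2])
  nid <- function(i, j) j * (nx + 1L) + i + 1L   # i in 0..nx, j in 0..ny
  nodes <- cbind(as.vector(X), as.vector(Y))
  ii <- rep(0:(nx - 1), ny); jj <- rep(0:(ny - 1), each = nx)
  elems <- cbind(nid(ii, jj), nid(ii + 1, jj), nid(ii + 1, jj + 1), nid(ii, jj + 1))
  region <- rep("trabecula", nrow(elems))

  sets <- list(
    trab_nodes = seq_len(nrow(nodes)),
    lateral_left = nid(0L, 0:ny),
    lateral_right = nid(nx, 0:ny),
    junction_bottom = nid(0:nx, 0L),
    junction_top = nid(0:nx, ny))
  edges <- rbind(
    data.frame(n1 = nid(0L, 0:(ny - 1)), n2 = nid(0L, 1:ny), tag = "lateral_left"),
    data.frame(n1 = nid(nx, 0:(ny - 1)), n2 = nid(nx, 1:ny), tag = "lateral_right"),
    data.frame(n1 = nid(0:(nx - 1), 0L), n2 = nid(1:nx, 0L), tag = "junction_bottom"),
    data.frame(n1 = nid(0:(nx - 1), ny), n2 = nid(1:nx, ny), tag = "junction_top"))
  ties <- list()

  if (plates) {
    y_bot <- mean(c(L[1, 2], R[1, 2]))
    y_top <- mean(c(L[ny + 1, 2], R[ny + 1, 2]))
    if (max(abs(c(L[1, 2] - R[1, 2], L[ny + 1, 2] - R[ny + 1, 2]))) > 1e-6) {
      stop("plates require horizontal trabecula end edges")
    }
    pw <- geometry$plates$w; pt <- geometry$plates$t
    npx <- max(4L, as.integer(round(pw / h_plate)))
    npy <- max(2L, as.integer(round(pt / h_plate)))
    add_plate <- function(y0, y1, label, nodes, elems, region, edges, sets) {
      off <- nrow(nodes)
      gx <- seq(-pw / 2, pw / 2, length.out = npx + 1)
      gy <- seq(y0, y1, length.out = npy + 1)
      pn <- cbind(rep(gx, npy + 1), rep(gy, each = npx + 1))
      pid <- function(i, j) off + j * (npx + 1L) + i + 1L
      ii <- rep(0:(npx - 1), npy); jj <- rep(0:(npy - 1), each = npx)
      pe <- cbind(pid(ii, jj), pid(ii + 1, jj), pid(ii + 1, jj + 1), pid(ii, jj + 1))
      nodes <- rbind(nodes, pn)
      elems <- rbind(elems, pe)
      region <- c(region, rep(label, nrow(pe)))
      sets[[paste0(label, "_nodes")]] <- (off + 1L):nrow(nodes)
      jout <- if (label == "plate_top") npy else 0L   # outer horizontal edge
      jin <- if (label == "plate_top") 0L else npy    # face towards trabecula
      sets[[paste0(label, "_outer_edge")]] <- pid(0:npx, jout)
      sets[[paste0(label, "_face")]] <- pid(0:npx, jin)
      edges <- rbind(edges, data.frame(
        n1 = pid(0:(npx - 1), jout), n2 = pid(1:npx, jout),
        tag = paste0(label, if (label == "plate_top") "_top_edge" else "_bottom_edge")))
      list(nodes = nodes, elems = elems, region = region, edges = edges,
           sets = sets, face_x = gx, face_ids = pid(0:npx, jin))
    }
    pb <- add_plate(y_bot - pt, y_bot, "plate_bottom", nodes, elems, region, edges, sets)
    pt_ <- add_plate(y_top, y_top + pt, "plate_top", pb$nodes, pb$elems, pb$region,
                     pb$edges, pb$sets)
    nodes <- pt_$nodes; elems <- pt_$elems; region <- pt_$region
    edges <- pt_$edges; sets <- pt_$sets
    ties <- c(
      make_ties(sets$junction_bottom, nodes, pb$face_x, pb$face_ids),
      make_ties(sets$junction_top, nodes, pt_$face_x, pt_$face_ids))
  }

  mesh <- structure(list(nodes = nodes, elems = elems, region = region,
                         sets = sets, ties = ties, edges = edges, h = h,
                         nx = nx, ny = ny),
                    class = "fe_mesh")
  if (min_jacobian(mesh) <= 0) {
    stop("meshing failure: inverted element (degenerate geometry); ",
         "central width ", signif(central_width(geometry), 4), " mm")
  }
  mesh
}

# linear-interpolation tie constraints of slave nodes onto a 1D face grid
make_ties <- function(slaves, nodes, face_x, face_ids) {
  lapply(slaves, function(s) {
    x <- nodes[s, 1]
    if (x < face_x[1] - 1e-9 || x > face_x[length(face_x)] + 1e-9) {
      stop("trabecula junction node outside the plate face")
    }
    k <- findInterval(x, face_x, rightmost.closed = TRUE, all.inside = TRUE)
    w2 <- (x - face_x[k]) / (face_x[k + 1] - face_x[k])
    list(slave = s, masters = c(face_ids[k], face_ids[k + 1]), w = c(1 - w2, w2))
  })
}

#' Structured rectangular mesh
#'
#' Low-level helper building a structured quadrilateral mesh of an axis
#' aligned rectangle, used for verification problems such as the confined
#' consolidation column.
#'
#' @param x0,x1,y0,y1 rectangle extents (mm)
#' @param nx,ny element counts
#' @param region region label for all elements
#' @return an `fe_mesh` with node sets `left`, `right`, `bottom`, `top`
#' @export
rect_mesh <- function(x0, x1, y0, y1, nx, ny, region = "trabecula") {
  gx <- seq(x0, x1, length.out = nx + 1)
  gy <- seq(y0, y1, length.out = ny + 1)
  nodes <- cbind(rep(gx, ny + 1), rep(gy, each = nx + 1))
  nid <- function(i, j) j * (nx + 1L) + i + 1L
  ii <- rep(0:(nx - 1), ny); jj <- rep(0:(ny - 1), each = nx)
  elems <- cbind(nid(ii, jj), nid(ii + 1, jj), nid(ii + 1, jj + 1), nid(ii, jj + 1))
  sets <- list(trab_nodes = seq_len(nrow(nodes)),
               left = nid(0L, 0:ny), right = nid(nx, 0:ny),
               bottom = nid(0:nx, 0L), top = nid(0:nx, ny))
  structure(list(nodes = nodes, elems = elems,
                 region = rep(region, nrow(elems)), sets = sets,
                 ties = list(), edges = NULL, h = (x1 - x0) / nx,
                 nx = nx, ny = ny),
            class = "fe_mesh")
}

#' Minimum Jacobian determinant over all elements and integration points
#'
#' Positive values certify a valid (non-inverted) mesh.
#'
#' @param mesh an `fe_mesh`
#' @return the minimum Jacobian determinant (mm^2)
#' @export
min_jacobian <- function(mesh) {
  g <- 1 / sqrt(3)
  gp <- cbind(c(-g, g, g, -g), c(-g, -g, g, g))
  Xe <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  Ye <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  mins <- Inf
  for (k in 1:4) {
    d <- quad_dshape(gp[k, 1], gp[k, 2])
    J11 <- Xe %*% d[, 1]; J12 <- Ye %*% d[, 1]
    J21 <- Xe %*% d[, 2]; J22 <- Ye %*% d[, 2]
    mins <- min(mins, J11 * J22 - J12 * J21)
  }
  mins
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh: %d nodes, %d elements (%s)\n", nrow(x$nodes),
              nrow(x$elems), paste(names(table(x$region)), collapse = ", ")))
  invisible(x)
}
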