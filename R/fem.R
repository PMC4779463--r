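#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @importFrom stats lm coef median predict
#' @importFrom utils write.csv
NULL

# bilinear quad shape functions and derivatives on the reference square
quad_shape <- function(xi, eta) {
  0.25 * c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta))
}

quad_dshape <- function(xi, eta) {
  cbind(0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
        0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)))
}

plane_strain_D <- function(E, nu) {
  c0 <- E / ((1 + nu) * (1 - 2 * nu))
  matrix(c0 * c(1 - nu, nu, 0, nu, 1 - nu, 0, 0, 0, (1 - 2 * nu) / 2), 3, 3)
}

plane_stress_D <- function(E, nu) {
  c0 <- E / (1 - nu^2)
  matrix(c0 * c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

# Vectorised element integrals for a group of quads.
# Returns per-element matrices flattened column-major:
#   K: 8x8 (dof order ux1..4, uy1..4), and if poro: Q (8x4), H, S, Me (4x4),
#   b (4), area.
group_integrals <- function(Xe, Ye, D, poro, material = NULL) {
  m <- nrow(Xe)
  g <- 1 / sqrt(3)
  gp <- cbind(c(-g, g, g, -g), c(-g, -g, g, g))
  Kxx <- Kxy <- Kyx <- Kyy <- matrix(0, m, 16)
  if (poro) {
    Qx <- Qy <- matrix(0, m, 16)
    H <- S <- Me <- matrix(0, m, 16)
    bN <- matrix(0, m, 4); area <- numeric(m)
    co <- material$kappa / material$mu
    Minv <- 1 / material$M
    alpha <- material$alpha
  }
  idx <- function(a, b) (b - 1L) * 4L + a
  for (k in 1:4) {
    d <- quad_dshape(gp[k, 1], gp[k, 2])
    N <- quad_shape(gp[k, 1], gp[k, 2])
    J11 <- drop(Xe %*% d[, 1]); J12 <- drop(Ye %*% d[, 1])
    J21 <- drop(Xe %*% d[, 2]); J22 <- drop(Ye %*% d[, 2])
    detJ <- J11 * J22 - J12 * J21
    dNdx <- matrix(0, m, 4); dNdy <- matrix(0, m, 4)
    for (a in 1:4) {
      dNdx[, a] <- (J22 * d[a, 1] - J12 * d[a, 2]) / detJ
      dNdy[, a] <- (-J21 * d[a, 1] + J11 * d[a, 2]) / detJ
    }
    w <- detJ  # unit gauss weights
    for (b in 1:4) {
      for (a in 1:4) {
        i <- idx(a, b)
        Kxx[, i] <- Kxx[, i] + w * (D[1, 1] * dNdx[, a] * dNdx[, b] +
                                      D[3, 3] * dNdy[, a] * dNdy[, b])
        Kyy[, i] <- Kyy[, i] + w * (D[2, 2] * dNdy[, a] * dNdy[, b] +
                                      D[3, 3] * dNdx[, a] * dNdx[, b])
        Kxy[, i] <- Kxy[, i] + w * (D[1, 2] * dNdx[, a] * dNdy[, b] +
                                      D[3, 3] * dNdy[, a] * dNdx[, b])
        Kyx[, i] <- Kyx[, i] + w * (D[1, 2] * dNdy[, a] * dNdx[, b] +
                                      D[3, 3] * dNdx[, a] * dNdy[, b])
        if (poro) {
          Qx[, i] <- Qx[, i] + w * alpha * dNdx[, a] * N[b]
          Qy[, i] <- Qy[, i] + w * alpha * dNdy[, a] * N[b]
          H[, i] <- H[, i] + w * co * (dNdx[, a] * dNdx[, b] + dNdy[, a] * dNdy[, b])
          S[, i] <- S[, i] + w * Minv * N[a] * N[b]
          Me[, i] <- Me[, i] + w * N[a] * N[b]
        }
      }
    }
    if (poro) {
      bN <- bN + w %o% N
      area <- area + w
    }
  }
  out <- list(Kxx = Kxx, Kxy = Kxy, Kyx = Kyx, Kyy = Kyy)
  if (poro) out <- c(out, list(Qx = Qx, Qy = Qy, H = H, S = S, Me = Me,
                               bN = bN, area = area))
  out
}

# triplets for a 4x4 nodal block: rows indexed by rdof[,a], cols by cdof[,b]
block_triplets <- function(vals, rdof, cdof) {
  list(i = as.vector(rdof[, rep(1:4, times = 4)]),
       j = as.vector(cdof[, rep(1:4, each = 4)]),
       x = as.vector(vals))
}

# Full-system assembly.
# Dof numbering: ux_i = i, uy_i = ndn + i, p = 2*ndn + pmap[node].
# Returns triplet lists for the blocks K (u-u), Q (u rows, p cols), and the
# p-p operators H, S, Sstab, all in global dof numbering, so callers can
# combine them into system matrices with a single sparseMatrix() call.
assemble_biot <- function(mesh, material, stabilize = TRUE,
                          plate_material = NULL) {
  ndn <- nrow(mesh$nodes)
  ptag <- mesh$region == "trabecula"
  pnodes <- sort(unique(as.vector(mesh$elems[ptag, , drop = FALSE])))
  pmap <- rep(NA_integer_, ndn); pmap[pnodes] <- seq_along(pnodes)
  np <- length(pnodes)
  ndof <- 2L * ndn + np

  acc <- list(K = list(), Q = list(), H = list(), S = list(), Sstab = list())
  for (reg in unique(mesh$region)) {
    sel <- mesh$region == reg
    el <- mesh$elems[sel, , drop = FALSE]
    Xe <- matrix(mesh$nodes[el, 1], ncol = 4)
    Ye <- matrix(mesh$nodes[el, 2], ncol = 4)
    poro <- reg == "trabecula"
    if (poro) {
      D <- plane_strain_D(material$E, material$nu)
      gi <- group_integrals(Xe, Ye, D, TRUE, material)
    } else {
      pm <- plate_material %||% material
      D <- plane_stress_D(pm$E, pm$nu)
      gi <- group_integrals(Xe, Ye, D, FALSE)
    }
    ux <- el; uy <- el + ndn
    acc$K <- c(acc$K, list(block_triplets(gi$Kxx, ux, ux),
                           block_triplets(gi$Kxy, ux, uy),
                           block_triplets(gi$Kyx, uy, ux),
                           block_triplets(gi$Kyy, uy, uy)))
    if (poro) {
      pd <- matrix(2L * ndn + pmap[el], ncol = 4)
      acc$Q <- c(acc$Q, list(block_triplets(gi$Qx, ux, pd),
                             block_triplets(gi$Qy, uy, pd)))
      acc$H <- c(acc$H, list(block_triplets(gi$H, pd, pd)))
      acc$S <- c(acc$S, list(block_triplets(gi$S, pd, pd)))
      if (stabilize) {
        # polynomial-pressure-projection stabilisation of the equal-order pair
        tau <- material$alpha^2 / (2 * material$G)
        st <- gi$Me
        for (b in 1:4) for (a in 1:4) {
          i <- (b - 1L) * 4L + a
          st[, i] <- tau * (st[, i] - gi$bN[, a] * gi$bN[, b] / gi$area)
        }
        acc$Sstab <- c(acc$Sstab, list(block_triplets(st, pd, pd)))
      }
    }
  }
  cat_trip <- function(l) {
    list(i = unlist(lapply(l, `[[`, "i"), use.names = FALSE),
         j = unlist(lapply(l, `[[`, "j"), use.names = FALSE),
         x = unlist(lapply(l, `[[`, "x"), use.names = FALSE))
  }
  out <- lapply(acc, cat_trip)
  c(out, list(ndof = ndof, ndn = ndn, pmap = pmap, pnodes = pnodes))
}

# one sparse matrix from a list of triplet sets (with optional scale factors)
triplets_to_sparse <- function(ndof, ..., scale = NULL, transpose = NULL) {
  parts <- list(...)
  scale <- scale %||% rep(1, length(parts))
  transpose <- transpose %||% rep(FALSE, length(parts))
  keep <- vapply(parts, function(t) length(t$i) > 0, logical(1))
  ii <- jj <- xx <- vector("list", length(parts))
  for (k in which(keep)) {
    t <- parts[[k]]
    ii[[k]] <- if (transpose[k]) t$j else t$i
    jj[[k]] <- if (transpose[k]) t$i else t$j
    xx[[k]] <- if (scale[k] == 1) t$x else scale[k] * t$x
  }
  Matrix::sparseMatrix(i = unlist(ii, use.names = FALSE),
                       j = unlist(jj, use.names = FALSE),
                       x = unlist(xx, use.names = FALSE),
                       dims = c(ndof, ndof))
}

# Build the constraint transformation u_full = T z.
# bcs fields used: fixed_nodes, fixed_ux_nodes, fixed_uy_nodes,
# direction_nodes + direction (unit vector), p_zero_nodes, ties come from the
# mesh. Masters of ties may themselves be direction-constrained.
build_transformation <- function(mesh, bcs, sys) {
  ndn <- sys$ndn; ndof <- sys$ndof
  code <- integer(ndof)  # 0 free, 1 fixed, 2 direction, 3 slave
  for (n in bcs$fixed_nodes) code[c(n, n + ndn)] <- 1L
  code[bcs$fixed_ux_nodes] <- 1L
  code[bcs$fixed_uy_nodes + ndn] <- 1L
  lam <- rep(NA_integer_, ndn)
  dirn <- bcs$direction_nodes
  if (length(dirn)) code[c(dirn, dirn + ndn)] <- 2L
  for (tie in mesh$ties) code[c(tie$slave, tie$slave + ndn)] <- 3L
  pz <- bcs$p_zero_nodes
  if (length(pz)) {
    pd <- 2L * ndn + sys$pmap[pz]
    code[pd[!is.na(pd)]] <- 1L
  }
  free <- which(code == 0L)
  colof <- rep(NA_integer_, ndof)
  colof[free] <- seq_along(free)
  ncol0 <- length(free)
  if (length(dirn)) {
    lam[dirn] <- ncol0 + seq_along(dirn)
    ncol0 <- ncol0 + length(dirn)
  }
  ti <- as.integer(free); tj <- colof[free]; tx <- rep(1, length(free))
  if (length(dirn)) {
    e <- bcs$direction
    ti <- c(ti, dirn, dirn + ndn)
    tj <- c(tj, lam[dirn], lam[dirn])
    tx <- c(tx, rep(e[1], length(dirn)), rep(e[2], length(dirn)))
  }
  for (tie in mesh$ties) {
    for (comp in 0:1) {
      sd <- tie$slave + comp * ndn
      for (k in seq_along(tie$masters)) {
        mn <- tie$masters[k]; md <- mn + comp * ndn; w <- tie$w[k]
        if (code[md] == 0L) {
          ti <- c(ti, sd); tj <- c(tj, colof[md]); tx <- c(tx, w)
        } else if (code[md] == 2L) {
          ti <- c(ti, sd); tj <- c(tj, lam[mn])
          tx <- c(tx, w * bcs$direction[comp + 1])
        } # fixed master contributes nothing
      }
    }
  }
  T <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ndof, ncol0))
  list(T = T, nred = ncol0, code = code, colof = colof, lam = lam)
}

# external nodal force vector at unit load scale
load_vector <- function(bcs, sys) {
  f <- numeric(sys$ndof)
  if (!is.null(bcs$loads)) {
    f[bcs$loads$node] <- f[bcs$loads$node] + bcs$loads$fx
    f[bcs$loads$node + sys$ndn] <- f[bcs$loads$node + sys$ndn] + bcs$loads$fy
  }
  f
}

#' Solve the transient Biot poroelasticity problem for one load pulse
#'
#' Assembles the fully coupled displacement-pressure system on the given mesh
#' (plane-strain poroelastic quadrilaterals in the trabecula, drained
#' plane-stress elastic quadrilaterals in the plates) and marches the load
#' pulse with backward Euler time integration, the load interpolated at the
#' increment endpoints by the pulse profile. Equal-order interpolation is used
#' for displacement and pressure, with an optional (default on) local
#' pressure-projection stabilisation term.
#'
#' @param mesh an `fe_mesh`
#' @param material a `poroelastic_material`
#' @param pulse a `load_pulse`
#' @param bcs boundary conditions, usually from [standard_bcs()],
#'   [column_bcs()] or [validation_bcs()]
#' @param stabilize logical, include the pressure stabilisation term
#' @return an object of class `transient_result` holding per-increment nodal
#'   displacements `U` (nodes x 2 x nstep, mm) and pore pressures `P`
#'   (nodes x nstep, N/mm^2), per-element Darcy flux vectors `q`
#'   (trabecula elements x 2 x nstep, mm/s), flux magnitudes `qmag`, element
#'   centroids, and bookkeeping needed to evaluate derived fields
#' @export
solve_transient <- function(mesh, material, pulse, bcs, stabilize = TRUE) {
  sys <- assemble_biot(mesh, material, stabilize = stabilize,
                       plate_material = bcs$plate_material)
  tr <- build_transformation(mesh, bcs, sys)
  dt <- pulse$increment
  ndn <- sys$ndn; ndof <- sys$ndof
  # u rows: K u - Q p; p rows: Q^T u + (S + Sstab + dt H) p
  A <- triplets_to_sparse(ndof, sys$K, sys$Q, sys$Q, sys$S, sys$Sstab, sys$H,
                          scale = c(1, -1, 1, 1, 1, dt),
                          transpose = c(FALSE, FALSE, TRUE, FALSE, FALSE,
                                        FALSE))
  Ared <- Matrix::crossprod(tr$T, A %*% tr$T)
  f0 <- load_vector(bcs, sys)
  scales <- pulse_profile(pulse)
  nstep <- pulse$nstep

  contact <- bcs$contact
  has_contact <- !is.null(contact)
  nred <- tr$nred
  if (has_contact) {
    cand <- contact$nodes
    gap0 <- contact$plane - mesh$nodes[cand, 2]
    kc <- contact$penalty %||% 1e6
    Trows <- tr$T[cand + ndn, , drop = FALSE]  # uy rows of candidates
    active <- which(gap0 < 1e-8)
    if (!length(active)) active <- which.min(gap0)
  }

  make_solver <- function(Ause) {
    lu <- Matrix::lu(Ause)
    function(b) Matrix::solve(lu, b)
  }
  if (!has_contact) solver <- make_solver(Ared)

  U <- array(0, c(ndn, 2, nstep))
  Pn <- matrix(0, ndn, nstep)
  uprev <- numeric(ndof)  # full dof vector of previous increment
  # rhs operator on the previous state: Q^T u_prev + (S + Sstab) p_prev
  QS <- triplets_to_sparse(ndof, sys$Q, sys$S, sys$Sstab,
                           transpose = c(TRUE, FALSE, FALSE))
  prow <- (2 * ndn + 1):ndof

  for (k in seq_len(nstep)) {
    rhs_full <- scales[k] * f0
    rhs_full[prow] <- (QS %*% uprev)[prow]
    b <- as.numeric(Matrix::crossprod(tr$T, rhs_full))
    if (!has_contact) {
      z <- as.numeric(solver(b))
      full <- as.numeric(tr$T %*% z)
    } else {
      Pk <- (contact$P %||% 0) * scales[k]
      for (it in 1:8) {
        na <- length(active)
        Ta <- Trows[active, , drop = FALSE]
        pen <- kc * Matrix::crossprod(Ta)           # sum t t^T
        tsum <- kc * Matrix::colSums(Ta)
        Aaug <- rbind(cbind(Ared + pen, -tsum), c(-tsum, kc * na))
        g_act <- gap0[active]
        baug <- c(b + kc * as.numeric(Matrix::crossprod(Ta, g_act)),
                  -Pk - kc * sum(g_act))
        zz <- as.numeric(Matrix::solve(Aaug, baug))
        z <- zz[1:nred]; wplate <- zz[nred + 1]
        uyc <- as.numeric(Trows %*% z)
        fc <- kc * (uyc - wplate - gap0)  # >0 where pushing into the plate
        newactive <- which(fc > 0)
        if (!length(newactive)) newactive <- which.min(gap0)
        if (identical(newactive, active)) break
        active <- newactive
      }
      full <- as.numeric(tr$T %*% z)
    }
    U[, 1, k] <- full[1:ndn]
    U[, 2, k] <- full[(ndn + 1):(2 * ndn)]
    Pn[sys$pnodes, k] <- full[prow]
    uprev <- full
  }

  # Darcy flux at trabecula element centroids, per increment
  sel <- mesh$region == "trabecula"
  el <- mesh$elems[sel, , drop = FALSE]
  Xe <- matrix(mesh$nodes[el, 1], ncol = 4)
  Ye <- matrix(mesh$nodes[el, 2], ncol = 4)
  d <- quad_dshape(0, 0)
  J11 <- drop(Xe %*% d[, 1]); J12 <- drop(Ye %*% d[, 1])
  J21 <- drop(Xe %*% d[, 2]); J22 <- drop(Ye %*% d[, 2])
  detJ <- J11 * J22 - J12 * J21
  dNdx <- dNdy <- matrix(0, nrow(el), 4)
  for (a in 1:4) {
    dNdx[, a] <- (J22 * d[a, 1] - J12 * d[a, 2]) / detJ
    dNdy[, a] <- (-J21 * d[a, 1] + J11 * d[a, 2]) / detJ
  }
  co <- material$kappa / material$mu
  q <- array(0, c(nrow(el), 2, nstep))
  for (k in seq_len(nstep)) {
    pe <- matrix(Pn[el, k], ncol = 4)
    q[, 1, k] <- -co * rowSums(dNdx * pe)
    q[, 2, k] <- -co * rowSums(dNdy * pe)
  }
  qmag <- sqrt(q[, 1, ]^2 + q[, 2, ]^2)
  if (nstep == 1L) qmag <- matrix(qmag, ncol = 1L)
  centroids <- cbind(rowMeans(Xe), rowMeans(Ye))

  structure(list(U = U, P = Pn, q = q, qmag = qmag, centroids = centroids,
                 elem_ids = which(sel), mesh = mesh, material = material,
                 pulse = pulse, times = seq_len(nstep) * dt,
                 dNdx = dNdx, dNdy = dNdy),
            class = "transient_result")
}

#' Darcy flux of one element at one increment
#'
#' Evaluates q = -(kappa/mu) grad p at the element centroid from the solved
#' pressure field.
#'
#' @param result a `transient_result`
#' @param element trabecula element index (into the trabecula element list)
#' @param increment time increment index (1-based)
#' @return length-2 flux vector (mm/s)
#' @export
darcy_flux <- function(result, element, increment) {
  result$q[element, , increment]
}

#' Element strain, stress and fluid-content fields at one increment
#'
#' Centroid values for the trabecula elements: small-strain tensor components,
#' effective and total stress (sigma = sigma' - alpha p I), fluid content
#' variation zeta = p/M + alpha * eps_kk.
#'
#' @param result a `transient_result`
#' @param increment increment index
#' @return tibble with one row per trabecula element
#' @export
element_fields <- function(result, increment) {
  mesh <- result$mesh; mat <- result$material
  el <- mesh$elems[result$elem_ids, , drop = FALSE]
  ux <- matrix(result$U[el, 1, increment], ncol = 4)
  uy <- matrix(result$U[el, 2, increment], ncol = 4)
  pe <- rowMeans(matrix(result$P[el, increment], ncol = 4))
  exx <- rowSums(result$dNdx * ux)
  eyy <- rowSums(result$dNdy * uy)
  gxy <- rowSums(result$dNdy * ux) + rowSums(result$dNdx * uy)
  D <- plane_strain_D(mat$E, mat$nu)
  sxx_eff <- D[1, 1] * exx + D[1, 2] * eyy
  syy_eff <- D[1, 2] * exx + D[2, 2] * eyy
  sxy <- D[3, 3] * gxy
  tibble::tibble(
    element = seq_len(nrow(el)),
    eps_xx = exx, eps_yy = eyy, gamma_xy = gxy,
    sigma_xx_eff = sxx_eff, sigma_yy_eff = syy_eff, sigma_xy = sxy,
    sigma_xx = sxx_eff - mat$alpha * pe,
    sigma_yy = syy_eff - mat$alpha * pe,
    p = pe,
    zeta = pe / mat$M + mat$alpha * (exx + eyy))
}
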