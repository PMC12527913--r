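# Plane-stress Q4 finite-element core.
#
# Bilinear isoparametric quadrilaterals with selective reduced integration:
# normal strains at 2x2 Gauss points, the shear term at the element center,
# which removes parasitic shear locking in bending-dominated states while
# keeping the patch test exact.

# structured grid in parametric (s, d) space; mapping supplied by caller
fe_mesh_grid <- function(sg, dg, map) {
  ns <- length(sg) - 1L; nd <- length(dg) - 1L
  S <- matrix(rep(sg, nd + 1L), ns + 1L, nd + 1L)
  Dm <- matrix(rep(dg, each = ns + 1L), ns + 1L, nd + 1L)
  xy <- map(as.vector(S), as.vector(Dm))
  nid <- function(i, j) (j - 1L) * (ns + 1L) + i
  ii <- rep(seq_len(ns), nd); jj <- rep(seq_len(nd), each = ns)
  elems <- cbind(nid(ii, jj), nid(ii + 1L, jj),
                 nid(ii + 1L, jj + 1L), nid(ii, jj + 1L))
  list(nodes = xy, param = cbind(as.vector(S), as.vector(Dm)),
       elems = elems, ns = ns, nd = nd,
       ec_s = (sg[ii] + sg[ii + 1L]) / 2, ec_d = (dg[jj] + dg[jj + 1L]) / 2)
}

fe_elem_areas <- function(mesh) {
  X <- matrix(mesh$nodes[mesh$elems, 1], ncol = 4)
  Y <- matrix(mesh$nodes[mesh$elems, 2], ncol = 4)
  0.5 * abs((X[, 1] - X[, 3]) * (Y[, 2] - Y[, 4]) -
            (X[, 2] - X[, 4]) * (Y[, 1] - Y[, 3]))
}

# Gauss rule: 4 points (2x2, weight 1) for normal strains, 1 center point
# (weight 4) for shear
fe_gauss <- function() {
  g <- 1 / sqrt(3)
  list(pts = rbind(c(-g, -g), c(g, -g), c(g, g), c(-g, g), c(0, 0)),
       wts = c(1, 1, 1, 1, 4))
}

# per-element plane-stress moduli; E, nu vectors over elements
fe_assemble <- function(mesh, E, nu, sig0 = NULL) {
  ne <- nrow(mesh$elems); el <- mesh$elems
  X <- matrix(mesh$nodes[el, 1], ncol = 4)
  Y <- matrix(mesh$nodes[el, 2], ncol = 4)
  D11 <- E / (1 - nu^2); D12 <- nu * D11; G <- E / (2 * (1 + nu))
  gr <- fe_gauss()
  Ke <- array(0, c(ne, 8, 8)); fe <- matrix(0, ne, 8)
  dNdx_s <- dNdy_s <- vector("list", 5L); detJs <- matrix(0, ne, 5)
  for (q in 1:5) {
    xi <- gr$pts[q, 1]; eta <- gr$pts[q, 2]
    dNxi  <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    dNeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    J11 <- X %*% dNxi; J12 <- Y %*% dNxi
    J21 <- X %*% dNeta; J22 <- Y %*% dNeta
    detJ <- as.vector(J11 * J22 - J12 * J21)
    iJ11 <- as.vector(J22) / detJ; iJ12 <- -as.vector(J12) / detJ
    iJ21 <- -as.vector(J21) / detJ; iJ22 <- as.vector(J11) / detJ
    dNdx <- dNdy <- matrix(0, ne, 4)
    for (a in 1:4) {
      dNdx[, a] <- iJ11 * dNxi[a] + iJ12 * dNeta[a]
      dNdy[, a] <- iJ21 * dNxi[a] + iJ22 * dNeta[a]
    }
    dNdx_s[[q]] <- dNdx; dNdy_s[[q]] <- dNdy; detJs[, q] <- abs(detJ)
    w <- gr$wts[q] * abs(detJ)
    if (q <= 4) {
      for (a in 1:4) for (b in 1:4) {
        Ke[, 2*a-1, 2*b-1] <- Ke[, 2*a-1, 2*b-1] + D11 * dNdx[, a] * dNdx[, b] * w
        Ke[, 2*a-1, 2*b  ] <- Ke[, 2*a-1, 2*b  ] + D12 * dNdx[, a] * dNdy[, b] * w
        Ke[, 2*a  , 2*b-1] <- Ke[, 2*a  , 2*b-1] + D12 * dNdy[, a] * dNdx[, b] * w
        Ke[, 2*a  , 2*b  ] <- Ke[, 2*a  , 2*b  ] + D11 * dNdy[, a] * dNdy[, b] * w
      }
      if (!is.null(sig0)) for (a in 1:4) {
        fe[, 2*a-1] <- fe[, 2*a-1] - (dNdx[, a] * sig0[, 1] + dNdy[, a] * sig0[, 3]) * w
        fe[, 2*a  ] <- fe[, 2*a  ] - (dNdy[, a] * sig0[, 2] + dNdx[, a] * sig0[, 3]) * w
      }
    } else {
      for (a in 1:4) for (b in 1:4) {
        Ke[, 2*a-1, 2*b-1] <- Ke[, 2*a-1, 2*b-1] + G * dNdy[, a] * dNdy[, b] * w
        Ke[, 2*a-1, 2*b  ] <- Ke[, 2*a-1, 2*b  ] + G * dNdy[, a] * dNdx[, b] * w
        Ke[, 2*a  , 2*b-1] <- Ke[, 2*a  , 2*b-1] + G * dNdx[, a] * dNdy[, b] * w
        Ke[, 2*a  , 2*b  ] <- Ke[, 2*a  , 2*b  ] + G * dNdx[, a] * dNdx[, b] * w
      }
    }
  }
  dof <- cbind(2*el[,1]-1, 2*el[,1], 2*el[,2]-1, 2*el[,2],
               2*el[,3]-1, 2*el[,3], 2*el[,4]-1, 2*el[,4])
  ndof <- 2L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(
    i = as.vector(rep(dof, times = 8)),
    j = as.vector(dof[, rep(1:8, each = 8)]),
    x = as.vector(Ke), dims = c(ndof, ndof))
  f0 <- numeric(ndof)
  if (!is.null(sig0)) {
    tab <- rowsum(as.vector(fe), as.vector(dof))
    idx <- as.integer(rownames(tab))
    f0[idx] <- f0[idx] + tab[, 1]
  }
  list(K = K, f0 = f0, dNdx = dNdx_s, dNdy = dNdy_s, detJ = detJs,
       D11 = D11, D12 = D12, G = G, ndof = ndof)
}

# direct solve with Dirichlet elimination; returns u and relative residual
fe_solve_system <- function(asm, f, fixed_dofs, fixed_vals = NULL) {
  ndof <- asm$ndof
  u <- numeric(ndof)
  if (length(fixed_dofs)) {
    u[fixed_dofs] <- fixed_vals %||% 0
  }
  free <- setdiff(seq_len(ndof), fixed_dofs)
  rhs <- f[free] - as.vector(asm$K[free, fixed_dofs, drop = FALSE] %*% u[fixed_dofs])
  u[free] <- as.vector(Matrix::solve(asm$K[free, free], rhs))
  res <- as.vector(asm$K[free, free] %*% u[free]) - rhs
  denom <- max(sqrt(sum(rhs^2)), 1e-300)
  list(u = u, residual = sqrt(sum(res^2)) / denom)
}

# element mean strain/stress and strain-energy density integrand,
# consistent with the selective reduced integration of the stiffness
fe_element_state <- function(mesh, asm, u) {
  el <- mesh$elems; ne <- nrow(el)
  ux <- matrix(u[2 * el - 1], ncol = 4); uy <- matrix(u[2 * el], ncol = 4)
  exx <- eyy <- gxy <- wtot <- numeric(ne); Ue <- numeric(ne)
  for (q in 1:4) {
    dNdx <- asm$dNdx[[q]]; dNdy <- asm$dNdy[[q]]
    w <- asm$detJ[, q]
    exq <- rowSums(dNdx * ux); eyq <- rowSums(dNdy * uy)
    exx <- exx + exq * w; eyy <- eyy + eyq * w; wtot <- wtot + w
    Ue <- Ue + 0.5 * (asm$D11 * exq^2 + 2 * asm$D12 * exq * eyq +
                        asm$D11 * eyq^2) * w
  }
  dNdx <- asm$dNdx[[5]]; dNdy <- asm$dNdy[[5]]
  g0 <- rowSums(dNdy * ux) + rowSums(dNdx * uy)
  Ue <- Ue + 0.5 * asm$G * g0^2 * 4 * asm$detJ[, 5]
  exx <- exx / wtot; eyy <- eyy / wtot; gxy <- g0
  sxx <- asm$D11 * exx + asm$D12 * eyy
  syy <- asm$D12 * exx + asm$D11 * eyy
  sxy <- asm$G * gxy
  list(exx = exx, eyy = eyy, gxy = gxy,
       sxx = sxx, syy = syy, sxy = sxy, Ue = Ue, w = wtot)
}

# consistent nodal loads for a traction along a chain of boundary nodes;
# traction given per node as a 2-column matrix (force per unit length)
fe_edge_load <- function(nodes, chain, traction, ndof) {
  f <- numeric(ndof)
  for (k in seq_len(length(chain) - 1L)) {
    i <- chain[k]; j <- chain[k + 1L]
    L <- sqrt(sum((nodes[j, ] - nodes[i, ])^2))
    tm <- (traction[k, ] + traction[k + 1L, ]) / 2
    f[c(2*i-1, 2*i)] <- f[c(2*i-1, 2*i)] + tm * L / 2
    f[c(2*j-1, 2*j)] <- f[c(2*j-1, 2*j)] + tm * L / 2
  }
  f
}
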