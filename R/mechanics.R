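#' ER layout specification for the cell-front model
#'
#' Three idealized ER morphologies are compared at equal ER area: thin
#' tubules normal to the leading edge (`"perpendicular"`), a cluster of
#' tubules aligned with the edge (`"parallel"`), and one simply connected
#' dense slab behind the cortex (`"sheet"`).
#'
#' @param kind `"perpendicular"`, `"parallel"` or `"sheet"`.
#' @param phi ER area fraction of the domain (0 < phi < 0.5; default 0.15).
#' @param w_t Tubule width (micrometres; default 0.3).
#' @param n_t Number of perpendicular tubules (default 20).
#' @param n_p Number of parallel tubules in the cluster (default 8).
#' @param gap_p Spacing between parallel tubules (micrometres; default 0.45).
#' @return An object of class `er_layout`.
#' @export
er_layout <- function(kind = c("perpendicular", "parallel", "sheet"),
                      phi = 0.15, w_t = 0.3, n_t = 20L, n_p = 8L,
                      gap_p = 0.45) {
  kind <- match.arg(kind)
  if (phi <= 0 || phi >= 0.5) stopf("phi must lie in (0, 0.5)")
  structure(list(kind = kind, phi = phi, w_t = w_t, n_t = as.integer(n_t),
                 n_p = as.integer(n_p), gap_p = gap_p),
            class = "er_layout")
}

#' Material parameters of the cell-front model
#'
#' Cytoplasm and ER are linear elastic; the actin cortex is an elastic band
#' that carries a contractile active stress along the edge tangent in the
#' quasi-static limit. Stresses are in kilopascals (nN per square
#' micrometre), lengths in micrometres.
#'
#' @param E_cyt,nu_cyt Cytoplasm Young modulus (kPa) and Poisson ratio.
#' @param E_er,nu_er ER modulus and Poisson ratio; the ER must be stiffer
#'   than the cytoplasm to contribute structural resistance.
#' @param E_cortex,nu_cortex Cortex modulus and Poisson ratio.
#' @return An object of class `material_set`.
#' @export
material_set <- function(E_cyt = 1, nu_cyt = 0.45, E_er = 10, nu_er = 0.45,
                         E_cortex = 100, nu_cortex = 0.45) {
  Es <- c(E_cyt, E_er, E_cortex)
  nus <- c(nu_cyt, nu_er, nu_cortex)
  if (any(Es <= 0)) stopf("all moduli must be > 0")
  if (any(nus <= 0 | nus >= 0.5)) stopf("Poisson ratios must lie in (0, 0.5)")
  if (E_er <= E_cyt) stopf("E_er must exceed E_cyt")
  structure(list(E = Es, nu = nus), class = "material_set")
}

#' Load case: protrusion or contraction
#'
#' Protrusion is an outward normal traction on the leading edge (the
#' lamellipodial push); contraction is a contractile eigenstress along the
#' edge tangent in the cortex band (the purse-string tension).
#'
#' @param mode `"protrusion"` or `"contraction"`.
#' @param magnitude Positive load magnitude in kPa (default 0.1).
#' @return An object of class `load_case`.
#' @export
load_case <- function(mode = c("protrusion", "contraction"), magnitude = 0.1) {
  mode <- match.arg(mode)
  if (magnitude <= 0) stopf("magnitude must be > 0")
  structure(list(mode = mode, magnitude = magnitude), class = "load_case")
}

#' Build the meshed cell-front domain for one curvature and ER layout
#'
#' The domain is a cell-front slab of width `W` and depth `D` whose leading
#' edge is a circular arc of signed curvature `kappa` (straight when 0;
#' positive bulging into the gap). The mesh follows the edge-normal direction
#' near the front — so perpendicular tubules are exactly edge-normal — and
#' blends to a flat clamped rear. Element region labels partition the domain
#' into cytoplasm, ER (per `layout`, grown to the requested area fraction
#' within well under 1%) and a cortex band of thickness `t_c` along the
#' leading edge.
#'
#' @param kappa Signed edge curvature (per micrometre); requires
#'   `|kappa| < 2/W` so the arc fits the domain.
#' @param layout An [er_layout()].
#' @param W,D Domain width and depth (micrometres; defaults 20 x 15).
#' @param t_c Cortex thickness (micrometres; default 0.2).
#' @param mesh_size Target element size (micrometres; default 0.1). Must
#'   resolve the tubule width and cortex with at least 2 elements.
#' @return An object of class `cell_front_domain`.
#' @export
build_domain <- function(kappa, layout = er_layout(), W = 20, D = 15,
                         t_c = 0.2, mesh_size = 0.1) {
  if (!inherits(layout, "er_layout")) stopf("layout must be an er_layout")
  if (abs(kappa) >= 2 / W) stopf("|kappa| must be < 2/W so the arc fits the domain")
  if (mesh_size > layout$w_t / 2 + 1e-12) {
    stopf("unresolvable geometry: tubule width %g um needs >= 2 elements (mesh_size <= %g)",
          layout$w_t, layout$w_t / 2)
  }
  if (mesh_size > t_c / 2 + 1e-12) {
    stopf("unresolvable geometry: cortex thickness %g um needs >= 2 elements",
          t_c)
  }
  ns <- max(2L, round(W / mesh_size)); nd <- max(2L, round(D / mesh_size))
  sg <- seq(-W / 2, W / 2, length.out = ns + 1L)
  dg <- seq(0, D, length.out = nd + 1L)
  map <- front_map(kappa, D)
  mesh <- fe_mesh_grid(sg, dg, map)
  mesh$kappa <- kappa; mesh$W <- W; mesh$D <- D
  area <- fe_elem_areas(mesh)
  lab <- integer(nrow(mesh$elems))
  lab[mesh$ec_d < t_c] <- 2L
  target <- layout$phi * sum(area)
  s <- mesh$ec_s; d <- mesh$ec_d
  tube_centers <- NULL
  if (layout$kind == "perpendicular") {
    centers <- seq(-W / 2 + W / (2 * layout$n_t),
                   W / 2 - W / (2 * layout$n_t), length.out = layout$n_t)
    # snap centers onto element centers so each tube spans a symmetric set
    # of element columns (the bending/membrane split relies on this)
    s_vals <- sort(unique(s))
    centers <- vapply(centers, function(cc)
      s_vals[which.min(abs(s_vals - cc))], numeric(1))
    tube_centers <- centers
    nearest <- apply(abs(outer(s, centers, "-")), 1, min)
    cand <- which(nearest < layout$w_t / 2 - 1e-9 & d >= t_c)
    pri <- d[cand]
  } else if (layout$kind == "parallel") {
    # stack bands behind the cortex; extend the cluster deeper if the
    # domain geometry leaves the nominal band count short of the target area
    n_bands <- layout$n_p
    repeat {
      bands <- (t_c + 0.05) + (seq_len(n_bands) - 1L) * (layout$w_t + layout$gap_p)
      bands <- bands[bands + layout$w_t < D]
      inband <- rep(FALSE, length(d))
      for (b in bands) inband <- inband | (d >= b & d < b + layout$w_t)
      if (sum(area[inband]) >= 1.02 * target ||
          length(bands) < n_bands) break
      n_bands <- n_bands + 1L
    }
    cand <- which(inband)
    pri <- abs(s[cand])
  } else {
    cand <- which(d >= t_c)
    pri <- d[cand]
  }
  o <- cand[order(pri)]
  csum <- cumsum(area[o])
  k <- which.min(abs(csum - target))
  if (abs(csum[k] - target) / target > 0.01) {
    stopf("could not realize ER area fraction %.3g within 1%%", layout$phi)
  }
  lab[o[seq_len(k)]] <- 1L
  structure(list(mesh = mesh, labels = lab, areas = area,
                 er_area = csum[k], er_target = target,
                 kappa = kappa, W = W, D = D, t_c = t_c,
                 mesh_size = mesh_size, layout = layout,
                 tube_centers = tube_centers),
            class = "cell_front_domain")
}

#' @export
print.cell_front_domain <- function(x, ...) {
  cat(sprintf(
    "<cell_front_domain> kappa=%+.3g um^-1, %s ER (phi=%.3g), %d elements\n",
    x$kappa, x$layout$kind, x$er_area / sum(x$areas), nrow(x$mesh$elems)))
  invisible(x)
}

# parametric map (s, d) -> (x, y): leading edge at d = 0 is the arc, gap on
# the +y side; radial near the front, blended toward a flat rear at y = -D
front_map <- function(kappa, D) {
  function(s, d) {
    if (abs(kappa) < 1e-12) return(cbind(s, -d))
    R <- 1 / abs(kappa)
    d_rad <- if (kappa > 0) min(0.6 * D, 0.8 * R) else 0.6 * D
    th <- s / R
    dr <- pmin(d, d_rad)
    if (kappa > 0) {
      Xr <- (R - dr) * sin(th); Yr <- -R + (R - dr) * cos(th)
    } else {
      Xr <- (R + dr) * sin(th); Yr <- R - (R + dr) * cos(th)
    }
    tt <- pmax(0, (d - d_rad) / (D - d_rad))
    cbind((1 - tt) * Xr + tt * s, (1 - tt) * Yr + tt * (-D))
  }
}

# unit edge-tangent direction at parameter s (d ~ 0)
front_tangent <- function(kappa, s) {
  if (abs(kappa) < 1e-12) return(cbind(rep(1, length(s)), rep(0, length(s))))
  R <- 1 / abs(kappa); th <- s / R
  if (kappa > 0) cbind(cos(th), -sin(th)) else cbind(cos(th), sin(th))
}

fe_front_materials <- function(domain, materials) {
  list(E = materials$E[domain$labels + 1L], nu = materials$nu[domain$labels + 1L])
}

#' Solve the cell-front model for one load case
#'
#' Quasi-static small-strain plane-stress equilibrium with the rear edge
#' clamped and lateral edges free. Protrusion applies the outward normal
#' traction on the leading edge; contraction applies the tangential
#' contractile eigenstress in the cortex band. The linear system is solved
#' directly; the relative equilibrium residual is checked against 1e-8.
#'
#' @param domain A [build_domain()] result.
#' @param materials A [material_set()].
#' @param load A [load_case()].
#' @return An object of class `fe_solution` with nodal displacements `u`
#'   (micrometres), element strains/stresses, the strain-energy density `U`
#'   (kPa, i.e. energy per unit volume), `tip_disp_um` (displacement
#'   magnitude at the edge apex), `edge_disp_um` (mean displacement magnitude
#'   along the leading edge), and the solver `residual`.
#' @export
solve_front <- function(domain, materials = material_set(),
                        load = load_case()) {
  asm <- fe_front_assemble(domain, materials)
  fe_front_solve(domain, asm, load, materials)
}

# assembly is load-mode independent apart from the eigenstress force vector,
# so K is computed once and both load modes reuse it in sweeps
fe_front_assemble <- function(domain, materials) {
  mat <- fe_front_materials(domain, materials)
  fe_assemble(domain$mesh, mat$E, mat$nu)
}

fe_front_solve <- function(domain, asm, load, materials) {
  mesh <- domain$mesh
  ndof <- asm$ndof
  f <- numeric(ndof)
  if (load$mode == "protrusion") {
    top <- which(mesh$param[, 2] == 0)
    top <- top[order(mesh$param[top, 1])]
    tang <- front_tangent(domain$kappa, mesh$param[top, 1])
    nrm <- cbind(-tang[, 2], tang[, 1])
    flip <- nrm[, 2] < 0
    nrm[flip, ] <- -nrm[flip, ]
    f <- fe_edge_load(mesh$nodes, top, load$magnitude * nrm, ndof)
  } else {
    tang <- front_tangent(domain$kappa, mesh$ec_s)
    sig0 <- matrix(0, nrow(mesh$elems), 3)
    ix <- domain$labels == 2L
    sig0[ix, 1] <- -load$magnitude * tang[ix, 1]^2
    sig0[ix, 2] <- -load$magnitude * tang[ix, 2]^2
    sig0[ix, 3] <- -load$magnitude * tang[ix, 1] * tang[ix, 2]
    mat <- fe_front_materials(domain, materials)
    asm_f <- fe_assemble_load_only(mesh, mat$E, mat$nu, sig0)
    f <- asm_f
  }
  rear <- which(mesh$param[, 2] == domain$D)
  sol <- fe_solve_system(asm, f, c(2 * rear - 1, 2 * rear))
  if (sol$residual > 1e-8) {
    stopf("solver did not reach equilibrium (relative residual %.3g)", sol$residual)
  }
  st <- fe_element_state(mesh, asm, sol$u)
  V <- sum(domain$areas)
  apex <- which(mesh$param[, 1] == 0 & mesh$param[, 2] == 0)[1]
  if (is.na(apex)) apex <- which.min(abs(mesh$param[, 1]) + mesh$param[, 2])
  top <- which(mesh$param[, 2] == 0)
  um <- sqrt(sol$u[seq(1, ndof, 2)]^2 + sol$u[seq(2, ndof, 2)]^2)
  structure(list(u = sol$u, state = st, U = sum(st$Ue) / V,
                 tip_disp_um = um[apex], edge_disp_um = mean(um[top]),
                 residual = sol$residual, load = load,
                 converged = TRUE),
            class = "fe_solution")
}

# eigenstress consistent load vector only (stiffness not needed again)
fe_assemble_load_only <- function(mesh, E, nu, sig0) {
  ne <- nrow(mesh$elems); el <- mesh$elems
  X <- matrix(mesh$nodes[el, 1], ncol = 4)
  Y <- matrix(mesh$nodes[el, 2], ncol = 4)
  gr <- fe_gauss()
  fe <- matrix(0, ne, 8)
  for (q in 1:4) {
    xi <- gr$pts[q, 1]; eta <- gr$pts[q, 2]
    dNxi  <- 0.25 * c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta))
    dNeta <- 0.25 * c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi))
    J11 <- X %*% dNxi; J12 <- Y %*% dNxi
    J21 <- X %*% dNeta; J22 <- Y %*% dNeta
    detJ <- as.vector(J11 * J22 - J12 * J21)
    iJ11 <- as.vector(J22) / detJ; iJ12 <- -as.vector(J12) / detJ
    iJ21 <- -as.vector(J21) / detJ; iJ22 <- as.vector(J11) / detJ
    w <- abs(detJ)
    for (a in 1:4) {
      dNdx <- iJ11 * dNxi[a] + iJ12 * dNeta[a]
      dNdy <- iJ21 * dNxi[a] + iJ22 * dNeta[a]
      fe[, 2*a-1] <- fe[, 2*a-1] - (dNdx * sig0[, 1] + dNdy * sig0[, 3]) * w
      fe[, 2*a  ] <- fe[, 2*a  ] - (dNdy * sig0[, 2] + dNdx * sig0[, 3]) * w
    }
  }
  dof <- cbind(2*el[,1]-1, 2*el[,1], 2*el[,2]-1, 2*el[,2],
               2*el[,3]-1, 2*el[,3], 2*el[,4]-1, 2*el[,4])
  f <- numeric(2L * nrow(mesh$nodes))
  tab <- rowsum(as.vector(fe), as.vector(dof))
  idx <- as.integer(rownames(tab))
  f[idx] <- f[idx] + tab[, 1]
  f
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("<fe_solution> %s: U = %.5g kPa, tip %.4g um, residual %.1e\n",
              x$load$mode, x$U, x$tip_disp_um, x$residual))
  invisible(x)
}

#' Strain-energy density of a converged solution
#'
#' U = (1/V) (1/2) integral of stress : strain over the domain, evaluated by
#' elementwise Gaussian quadrature (kPa).
#'
#' @param sol An [solve_front()] solution.
#' @param domain The matching [build_domain()] domain.
#' @return Scalar strain-energy density.
#' @export
strain_energy_density <- function(sol, domain) {
  if (!isTRUE(sol$converged)) stopf("solution is not converged")
  sum(sol$state$Ue) / sum(domain$areas)
}

#' Split ER strain energy into membrane (stretch) and bending contributions
#'
#' ER element strain states are decomposed along each tubule or sheet
#' mid-axis (edge-normal for perpendicular tubules, edge-tangent for parallel
#' tubules and for the sheet, whose single axis is taken in the edge-tangent
#' frame): per cross-section, the area-mean axial strain carries the membrane
#' (stretch) energy, while the residual axial variation plus the
#' axial-transverse shear is the bending (curvature-change) contribution.
#'
#' @param sol An [solve_front()] solution.
#' @param domain The matching [build_domain()] domain.
#' @return Named numeric vector `c(membrane, bending)`, fractions summing
#'   to 1.
#' @export
energy_split <- function(sol, domain) {
  er <- which(domain$labels == 1L)
  if (!length(er)) stopf("ER region is empty")
  mesh <- domain$mesh
  el <- mesh$elems[er, , drop = FALSE]
  X <- matrix(mesh$nodes[el, 1], ncol = 4)
  Y <- matrix(mesh$nodes[el, 2], ncol = 4)
  ed <- cbind((X[, 4] + X[, 3] - X[, 1] - X[, 2]) / 2,
              (Y[, 4] + Y[, 3] - Y[, 1] - Y[, 2]) / 2)
  es <- cbind((X[, 2] + X[, 3] - X[, 1] - X[, 4]) / 2,
              (Y[, 2] + Y[, 3] - Y[, 1] - Y[, 4]) / 2)
  ax <- if (domain$layout$kind == "perpendicular") ed else es
  ax <- ax / sqrt(rowSums(ax^2))
  tr <- cbind(-ax[, 2], ax[, 1])
  st <- sol$state
  exx <- st$exx[er]; eyy <- st$eyy[er]; gxy <- st$gxy[er]
  sxx <- st$sxx[er]; syy <- st$syy[er]; sxy <- st$sxy[er]
  a1 <- ax[, 1]; a2 <- ax[, 2]; t1 <- tr[, 1]; t2 <- tr[, 2]
  e_ax <- a1^2 * exx + a2^2 * eyy + a1 * a2 * gxy
  s_ax <- a1^2 * sxx + a2^2 * syy + 2 * a1 * a2 * sxy
  g_at <- 2 * a1 * t1 * exx + 2 * a2 * t2 * eyy + (a1 * t2 + a2 * t1) * gxy
  t_at <- a1 * t1 * sxx + a2 * t2 * syy + (a1 * t2 + a2 * t1) * sxy
  w <- st$w[er]
  ecs <- mesh$ec_s[er]; ecd <- mesh$ec_d[er]
  if (domain$layout$kind == "perpendicular") {
    tube <- apply(abs(outer(ecs, domain$tube_centers, "-")), 1, which.min)
    cs <- paste(tube, round(ecd, 9))
  } else {
    cs <- as.character(round(ecs, 9))
  }
  E_ax <- sum(0.5 * s_ax * e_ax * w)
  memb <- vapply(split(seq_along(er), cs), function(ii) {
    wi <- w[ii]
    0.5 * (sum(s_ax[ii] * wi) / sum(wi)) * (sum(e_ax[ii] * wi) / sum(wi)) * sum(wi)
  }, numeric(1))
  E_memb <- sum(memb)
  E_sh <- sum(0.5 * t_at * g_at * w)
  tot <- E_ax + E_sh
  if (tot <= 0) return(c(membrane = NA_real_, bending = NA_real_))
  c(membrane = E_memb / tot, bending = ((E_ax - E_memb) + E_sh) / tot)
}

#' Sweep strain energies over curvature, ER layout and load mode
#'
#' Full factorial sweep. Within one (curvature, layout) cell the stiffness
#' matrix is assembled once and reused across load modes. Energies are also
#' reported normalized by the flat-edge (kappa = 0) perpendicular-layout
#' energy of the same load mode, which is computed on demand when not part of
#' the grid. Cases that fail to solve are flagged (`ok = FALSE`) without
#' aborting the sweep.
#'
#' @param kappas Signed curvatures (per micrometre).
#' @param layouts Character vector of layout kinds, or list of [er_layout()].
#' @param modes Load modes to run.
#' @param materials A [material_set()].
#' @param magnitude Load magnitude (kPa) for both modes.
#' @param phi ER area fraction passed to layouts given as kinds.
#' @param W,D,t_c,mesh_size Domain parameters, as in [build_domain()].
#' @param with_split Also compute the ER bending-energy fraction (slower).
#' @return A data frame of class `sweep_result` with columns
#'   `kappa_um_inv`, `layout`, `mode`, `U`, `U_norm`, `tip_disp_um`,
#'   `edge_disp_um`, `bend_frac`, `ok`.
#' @export
curvature_sweep <- function(kappas = c(0, seq(0.01, 0.08, by = 0.01)),
                            layouts = c("perpendicular", "parallel", "sheet"),
                            modes = c("protrusion", "contraction"),
                            materials = material_set(), magnitude = 0.1,
                            phi = 0.15, W = 20, D = 15, t_c = 0.2,
                            mesh_size = 0.1, with_split = TRUE) {
  if (!length(kappas)) stopf("kappas must be non-empty")
  if (is.character(layouts)) {
    layouts <- lapply(layouts, function(k) er_layout(k, phi = phi))
  }
  kinds <- vapply(layouts, function(l) l$kind, character(1))
  rows <- list()
  need_ref <- !any(kappas == 0) || !"perpendicular" %in% kinds
  ref_kappas <- if (need_ref) c(0) else c()
  for (k in unique(c(kappas, ref_kappas))) {
    lay_set <- layouts
    if (!k %in% kappas) lay_set <- list(er_layout("perpendicular", phi = phi))
    for (lay in lay_set) {
      res <- tryCatch({
        dom <- build_domain(k, lay, W = W, D = D, t_c = t_c,
                            mesh_size = mesh_size)
        asm <- fe_front_assemble(dom, materials)
        lapply(modes, function(md) {
          sol <- fe_front_solve(dom, asm, load_case(md, magnitude), materials)
          bf <- if (with_split) unname(energy_split(sol, dom)["bending"]) else NA_real_
          data.frame(kappa_um_inv = k, layout = lay$kind, mode = md,
                     U = sol$U, U_norm = NA_real_,
                     tip_disp_um = sol$tip_disp_um,
                     edge_disp_um = sol$edge_disp_um,
                     bend_frac = bf, ok = TRUE)
        })
      }, error = function(e) {
        lapply(modes, function(md)
          data.frame(kappa_um_inv = k, layout = lay$kind, mode = md,
                     U = NA_real_, U_norm = NA_real_, tip_disp_um = NA_real_,
                     edge_disp_um = NA_real_, bend_frac = NA_real_,
                     ok = FALSE))
      })
      rows <- c(rows, res)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("kappa_um_inv", "layout", "mode")]), ]
  for (md in unique(out$mode)) {
    ref <- out$U[out$mode == md & out$kappa_um_inv == 0 &
                   out$layout == "perpendicular"]
    if (length(ref) == 1 && is.finite(ref) && ref > 0) {
      out$U_norm[out$mode == md] <- out$U[out$mode == md] / ref
    }
  }
  keep <- out$kappa_um_inv %in% kappas
  out <- out[keep | !need_ref, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Rank ER layouts by strain energy for each curvature and load mode
#'
#' @param sweep A [curvature_sweep()] result covering all three layouts for
#'   each reported (curvature, mode); otherwise an error lists the missing
#'   cells. Energies within 0.1% of each other are reported as ties.
#' @return A data frame with one row per (kappa, mode): the ranking string
#'   (lowest energy first, `~` marking ties) and the pairwise gaps
#'   `gap_sheet_perp`, `gap_par_perp` (differences of `U`).
#' @export
ordering_report <- function(sweep) {
  need <- c("perpendicular", "parallel", "sheet")
  cells <- split(sweep, interaction(sweep$kappa_um_inv, sweep$mode, drop = TRUE))
  rows <- lapply(cells, function(d) {
    missing <- setdiff(need, d$layout[d$ok])
    if (length(missing)) {
      stopf("incomplete factorial: kappa=%g mode=%s missing %s",
            d$kappa_um_inv[1], d$mode[1], paste(missing, collapse = ", "))
    }
    d <- d[match(need, d$layout), ]
    o <- order(d$U)
    lab <- d$layout[o]
    sep <- ifelse(abs(diff(d$U[o])) <= 0.001 * pmax(d$U[o][-3], 1e-300),
                  " ~ ", " < ")
    data.frame(kappa_um_inv = d$kappa_um_inv[1], mode = d$mode[1],
               ranking = paste0(lab[1], sep[1], lab[2], sep[2], lab[3]),
               lowest = lab[1],
               gap_sheet_perp = d$U[d$layout == "sheet"] -
                 d$U[d$layout == "perpendicular"],
               gap_par_perp = d$U[d$layout == "parallel"] -
                 d$U[d$layout == "perpendicular"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mode, out$kappa_um_inv), ]
}
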