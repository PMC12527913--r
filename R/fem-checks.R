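# Standard solver verification problems with closed-form references.
# These exercise the same element, assembly and solve path as the cell-front
# model on simple rectangular domains.

fe_mesh_rect <- function(Lx, Ly, nx, ny, distort = 0) {
  sg <- seq(0, Lx, length.out = nx + 1L)
  dg <- seq(0, Ly, length.out = ny + 1L)
  mesh <- fe_mesh_grid(sg, dg, function(s, d) cbind(s, d))
  if (distort > 0) {
    # deterministic interior-node jiggle to make the patch test non-trivial
    p <- mesh$param
    interior <- p[, 1] > 0 & p[, 1] < Lx & p[, 2] > 0 & p[, 2] < Ly
    hx <- Lx / nx; hy <- Ly / ny
    ph <- sin(7 * p[, 1] / Lx + 3 * p[, 2] / Ly)
    mesh$nodes[interior, 1] <- mesh$nodes[interior, 1] +
      distort * hx * ph[interior]
    mesh$nodes[interior, 2] <- mesh$nodes[interior, 2] +
      distort * hy * cos(5 * p[interior, 1] / Lx)
  }
  mesh
}

#' Patch test: linear displacement field reproduced exactly
#'
#' Prescribes an arbitrary linear displacement on the boundary of a distorted
#' quadrilateral mesh; a consistent element must reproduce the uniform strain
#' state to machine precision in the interior.
#'
#' @param nx,ny Mesh divisions.
#' @param distort Relative interior-node distortion (default 0.2).
#' @return Maximum absolute deviation of any element strain component from
#'   the exact uniform strain.
#' @export
fe_patch_test <- function(nx = 6L, ny = 5L, distort = 0.2) {
  mesh <- fe_mesh_rect(2, 1.4, nx, ny, distort = distort)
  E <- rep(3, nrow(mesh$elems)); nu <- rep(0.3, nrow(mesh$elems))
  asm <- fe_assemble(mesh, E, nu)
  # u = a + B x (linear field): exact strains exx=B11, eyy=B22, gxy=B12+B21
  B <- matrix(c(2e-3, 1e-3, -5e-4, 3e-3), 2, 2)
  uex <- function(xy) cbind(1e-3 + xy %*% B[1, ], -2e-3 + xy %*% B[2, ])
  p <- mesh$param
  bnd <- which(p[, 1] %in% range(p[, 1]) | p[, 2] %in% range(p[, 2]))
  uval <- uex(mesh$nodes[bnd, , drop = FALSE])
  sol <- fe_solve_system(asm, numeric(asm$ndof),
                         c(2 * bnd - 1, 2 * bnd),
                         c(uval[, 1], uval[, 2]))
  st <- fe_element_state(mesh, asm, sol$u)
  max(abs(st$exx - B[1, 1]), abs(st$eyy - B[2, 2]),
      abs(st$gxy - (B[1, 2] + B[2, 1])))
}

#' Uniaxial bar: strain-energy density against sigma^2 / (2 E)
#'
#' A homogeneous bar clamped at one end (roller) and pulled by a uniform end
#' traction; compares the computed strain-energy density with the closed
#' form.
#'
#' @param sigma End traction (kPa).
#' @param E,nu Material parameters.
#' @param nx,ny Mesh divisions.
#' @return List with `U`, `U_exact` and the relative error `rel_err`.
#' @export
fe_uniaxial_bar <- function(sigma = 0.2, E = 5, nu = 0.3, nx = 40L, ny = 8L) {
  L <- 10; H <- 2
  mesh <- fe_mesh_rect(L, H, nx, ny)
  ne <- nrow(mesh$elems)
  asm <- fe_assemble(mesh, rep(E, ne), rep(nu, ne))
  p <- mesh$param
  left <- which(p[, 1] == 0)
  right <- which(p[, 1] == max(p[, 1]))
  right <- right[order(p[right, 2])]
  f <- fe_edge_load(mesh$nodes, right,
                    cbind(rep(sigma, length(right)), 0), asm$ndof)
  # left edge: u_x = 0; one node pinned in y to remove the rigid mode
  fixed <- c(2 * left - 1, 2 * left[1])
  sol <- fe_solve_system(asm, f, fixed)
  st <- fe_element_state(mesh, asm, sol$u)
  U <- sum(st$Ue) / (L * H)
  U_exact <- sigma^2 / (2 * E)
  list(U = U, U_exact = U_exact, rel_err = abs(U - U_exact) / U_exact)
}

#' Cantilever bending against Euler-Bernoulli beam theory
#'
#' Clamped-free slender beam with a transverse tip load; returns the FE tip
#' deflection and the beam-theory value P L^3 / (3 E I).
#'
#' @param L,H Beam length and thickness (slenderness L/H; default 10).
#' @param P Total tip load.
#' @param E,nu Material parameters.
#' @param nx,ny Mesh divisions.
#' @return List with `tip`, `tip_beam` and `rel_err`.
#' @export
fe_cantilever <- function(L = 20, H = 2, P = 0.01, E = 5, nu = 0.3,
                          nx = 80L, ny = 8L) {
  mesh <- fe_mesh_rect(L, H, nx, ny)
  ne <- nrow(mesh$elems)
  asm <- fe_assemble(mesh, rep(E, ne), rep(nu, ne))
  p <- mesh$param
  left <- which(p[, 1] == 0)
  right <- which(p[, 1] == max(p[, 1]))
  right <- right[order(p[right, 2])]
  f <- fe_edge_load(mesh$nodes, right,
                    cbind(0, rep(P / H, length(right))), asm$ndof)
  sol <- fe_solve_system(asm, f, c(2 * left - 1, 2 * left))
  tip_nodes <- right
  tip <- mean(sol$u[2 * tip_nodes])
  I <- H^3 / 12
  tip_beam <- P * L^3 / (3 * E * I)
  list(tip = tip, tip_beam = tip_beam, rel_err = abs(tip - tip_beam) / tip_beam)
}
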