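#' Algebraic (Taubin) circle fit
#'
#' Fits a circle to planar points by Taubin's algebraic least-squares method,
#' which is stable on short arcs such as a single cell's wound-edge segment.
#' Collinear input is reported as the zero-curvature (infinite radius) limit
#' rather than an error.
#'
#' @param points Two-column matrix of points (micrometres), or an
#'   [contour()] whose vertices are used.
#' @return A list of class `circle_fit` with `center`, `radius`,
#'   `kappa_mag` (= 1/radius, per micrometre), and `degenerate` (`TRUE` for
#'   collinear input, where `radius = Inf` and `kappa_mag = 0`).
#' @export
#' @examples
#' th <- seq(0, pi, length.out = 20)
#' fit_circle(cbind(10 * cos(th), 10 * sin(th)))$kappa_mag  # 0.1
fit_circle <- function(points) {
  if (inherits(points, "er_contour")) points <- points$vertices
  p <- matrix(as.numeric(points), ncol = 2)
  if (nrow(p) < 3L) stopf("fit_circle needs at least 3 points")
  xm <- mean(p[, 1]); ym <- mean(p[, 2])
  u <- p[, 1] - xm; v <- p[, 2] - ym
  # collinearity check on the centered covariance
  C <- crossprod(cbind(u, v)) / nrow(p)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0 || ev[2] / ev[1] < 1e-12) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          kappa_mag = 0, degenerate = TRUE),
                     class = "circle_fit"))
  }
  z <- u^2 + v^2
  zm <- mean(z)
  Z0 <- (z - zm) / (2 * sqrt(zm))
  M <- cbind(Z0, u, v)
  sv <- svd(M, nu = 0)
  A <- sv$v[, 3]
  A1 <- A[1] / (2 * sqrt(zm))
  A4 <- -zm * A1
  if (abs(A1) < 1e-12 * sqrt(sum(A[2:3]^2)) / max(sqrt(zm), 1)) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          kappa_mag = 0, degenerate = TRUE),
                     class = "circle_fit"))
  }
  cx <- -A[2] / (2 * A1); cy <- -A[3] / (2 * A1)
  r <- sqrt(A[2]^2 + A[3]^2 - 4 * A1 * A4) / (2 * abs(A1))
  structure(list(center = c(cx + xm, cy + ym), radius = r,
                 kappa_mag = 1 / r, degenerate = FALSE),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  if (x$degenerate) cat("<circle_fit> degenerate: zero curvature (radius = Inf)\n")
  else cat(sprintf("<circle_fit> center (%.3f, %.3f), radius %.3f um, |kappa| %.4g um^-1\n",
                   x$center[1], x$center[2], x$radius, x$kappa_mag))
  invisible(x)
}

#' Curvature profile of a contour by smoothing-spline fitting
#'
#' Fits smoothing splines x(t), y(t) against chordal arclength and evaluates
#' the planar curvature kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2),
#' resampled at uniform arclength. For closed contours the fit wraps around
#' the join. The smoothing level defaults to generalized cross-validation.
#'
#' @param ct A [contour()] with at least 6 vertices.
#' @param smoothing Optional positive smoothing parameter (passed as `spar`
#'   to [stats::smooth.spline()]); `NULL` selects it by GCV.
#' @param n_out Number of output samples along the contour.
#' @return A data frame of class `curvature_profile` with columns `s`
#'   (arclength, micrometres, strictly increasing) and `kappa`
#'   (per micrometre, signed by traversal orientation), with the smoothing
#'   used stored in `attr(, "smoothing")`.
#' @seealso [curvature_arc_mean()]
#' @export
spline_curvature <- function(ct, smoothing = NULL, n_out = 200L) {
  ct <- as_contour(ct, closed = FALSE)
  if (!is.null(smoothing) && smoothing <= 0) stopf("smoothing must be > 0")
  v <- ct$vertices
  if (nrow(v) < 6L) stopf("spline_curvature needs at least 6 vertices")
  wrap <- 0L
  if (ct$closed) {
    wrap <- min(nrow(v), 10L)
    v <- rbind(v[(nrow(v) - wrap + 1L):nrow(v), ], v, v[1:wrap, ])
  }
  tt <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  fit1 <- function(val) {
    if (is.null(smoothing)) stats::smooth.spline(tt, val, cv = FALSE)
    else stats::smooth.spline(tt, val, spar = smoothing)
  }
  fx <- fit1(v[, 1]); fy <- fit1(v[, 2])
  t0 <- tt[wrap + 1L]; t1 <- tt[length(tt) - wrap]
  tg <- seq(t0, t1, length.out = max(4L * n_out, 400L))
  x1 <- stats::predict(fx, tg, deriv = 1)$y
  y1 <- stats::predict(fy, tg, deriv = 1)$y
  sp <- sqrt(x1^2 + y1^2)
  s_dense <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tg)))
  s_out <- seq(0, s_dense[length(s_dense)], length.out = n_out)
  t_out <- stats::approx(s_dense, tg, xout = s_out, ties = "ordered")$y
  x1 <- stats::predict(fx, t_out, deriv = 1)$y
  y1 <- stats::predict(fy, t_out, deriv = 1)$y
  x2 <- stats::predict(fx, t_out, deriv = 2)$y
  y2 <- stats::predict(fy, t_out, deriv = 2)$y
  kappa <- (x1 * y2 - y1 * x2) / (x1^2 + y1^2)^1.5
  out <- data.frame(s = s_out, kappa = kappa)
  class(out) <- c("curvature_profile", "data.frame")
  attr(out, "smoothing") <- if (is.null(smoothing)) fx$spar else smoothing
  out
}

#' Arc-mean curvature over an arclength window
#'
#' Trapezoidal mean of `kappa(s)` over `[s1, s2]`.
#'
#' @param profile A `curvature_profile` from [spline_curvature()].
#' @param s1,s2 Arclength window (micrometres); defaults to the full profile.
#' @return Mean curvature (per micrometre).
#' @export
curvature_arc_mean <- function(profile, s1 = NULL, s2 = NULL) {
  s1 <- s1 %||% min(profile$s); s2 <- s2 %||% max(profile$s)
  if (s2 <= s1) stopf("need s2 > s1")
  ix <- profile$s >= s1 & profile$s <= s2
  if (sum(ix) < 2L) stopf("fewer than 2 samples in [s1, s2]")
  s <- profile$s[ix]; k <- profile$kappa[ix]
  sum((k[-1] + k[-length(k)]) / 2 * diff(s)) / (s[length(s)] - s[1])
}

#' Assign the wound-edge sign convention to a curvature magnitude
#'
#' Positive curvature means the edge bulges into the cell-free gap (convex
#' edge); negative means it indents into the monolayer (concave). The side is
#' resolved with a probe point known to lie in the gap: the osculating-circle
#' center lies on the monolayer side exactly when the probe falls outside the
#' fitted circle.
#'
#' @param kappa_mag Non-negative curvature magnitude (per micrometre).
#' @param edge A [contour()] tracing the edge (open arc).
#' @param gap_side_probe Length-2 point in the cell-free gap.
#' @return Signed curvature (per micrometre); 0 for a flat edge.
#' @export
assign_sign <- function(kappa_mag, edge, gap_side_probe) {
  if (kappa_mag < 0) stopf("kappa_mag must be non-negative")
  edge <- as_contour(edge, closed = FALSE)
  probe <- as.numeric(gap_side_probe)
  d_edge <- dist_to_contour(matrix(probe, ncol = 2), edge)
  if (d_edge < 1e-9) stopf("gap_side_probe lies on the edge")
  if (kappa_mag == 0) return(0)
  fit <- fit_circle(edge$vertices)
  if (fit$degenerate) return(0)
  d_center <- sqrt(sum((probe - fit$center)^2))
  if (d_center > fit$radius) kappa_mag else -kappa_mag
}

#' Fraction of a cell perimeter in contact with the wound edge
#'
#' Measures the arclength of the cell boundary lying within `tol` of the
#' wound-edge contour, divided by the full perimeter. Cells are included in
#' curvature analyses only when strictly more than 20% of their perimeter
#' touches the wound.
#'
#' @param cell Closed [contour()] of the cell.
#' @param wound_edge [contour()] of the wound boundary (same frame).
#' @param tol Contact distance (micrometres); defaults to one pixel
#'   equivalent when the cell records a `pixel_size`, else 1.
#' @return A list with `fraction` in \[0, 1\] and `include`
#'   (`fraction > 0.20`, strict).
#' @export
perimeter_contact_fraction <- function(cell, wound_edge, tol = NULL) {
  cell <- as_contour(cell)
  tol <- tol %||% cell$pixel_size %||% 1
  if (tol <= 0) stopf("tol must be > 0")
  v <- cell$vertices
  if (cell$closed) v <- rbind(v, v[1L, ])
  # resample boundary into short sub-segments and test their midpoints
  seg_len <- sqrt(rowSums(diff(v)^2))
  step <- max(min(tol / 4, sum(seg_len) / 2000), sum(seg_len) / 20000)
  mids <- NULL; lens <- NULL
  for (i in seq_len(nrow(v) - 1L)) {
    n_i <- max(1L, ceiling(seg_len[i] / step))
    tfrac <- (seq_len(n_i) - 0.5) / n_i
    mids <- rbind(mids, cbind(v[i, 1] + tfrac * (v[i + 1, 1] - v[i, 1]),
                              v[i, 2] + tfrac * (v[i + 1, 2] - v[i, 2])))
    lens <- c(lens, rep(seg_len[i] / n_i, n_i))
  }
  d <- dist_to_contour(mids, wound_edge)
  fraction <- sum(lens[d <= tol]) / sum(lens)
  list(fraction = fraction, include = fraction > 0.20)
}

#' Front region of interest of an edge cell
#'
#' Intersects the cell polygon with the band extending `d_front` micrometres
#' inward from the wound edge. The ROI boundary is extracted as the zero
#' level set of max(dist-to-edge - d_front, signed-dist-to-cell) on a fine
#' grid, so curved edges are handled without polygon clipping machinery.
#'
#' @param cell Closed [contour()] of the cell.
#' @param wound_edge [contour()] of the wound boundary.
#' @param d_front Band depth (micrometres; default 10).
#' @param grid_n Grid resolution along the longer bounding-box side.
#' @return A list of class `front_roi` with `polygon` (an [contour()]),
#'   `d_front`, `cell_id`, and `tangent_deg`, the wound-edge tangent angle
#'   (degrees, y-down frame) nearest the ROI centroid.
#' @export
front_roi <- function(cell, wound_edge, d_front = 10, grid_n = 400L) {
  cell <- as_contour(cell)
  if (d_front <= 0) stopf("d_front must be > 0")
  v <- cell$vertices
  rng_x <- range(v[, 1]); rng_y <- range(v[, 2])
  pad <- 0.02 * max(diff(rng_x), diff(rng_y))
  h <- (max(diff(rng_x), diff(rng_y)) + 2 * pad) / grid_n
  gx <- seq(rng_x[1] - pad, rng_x[2] + pad, by = h)
  gy <- seq(rng_y[1] - pad, rng_y[2] + pad, by = h)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  d_edge <- dist_to_contour(pts, wound_edge)
  d_cell <- dist_to_contour(pts, cell)
  inside <- points_in_contour(pts, cell)
  sd_cell <- ifelse(inside, -d_cell, d_cell)
  if (!any(inside & d_edge <= d_front)) stopf("cell not at edge")
  if (all(d_edge[inside] <= d_front)) {
    poly <- cell
  } else {
    g <- matrix(pmax(d_edge - d_front, sd_cell), nrow = length(gx))
    cl <- grDevices::contourLines(gx, gy, g, levels = 0)
    if (!length(cl)) stopf("cell not at edge")
    areas <- vapply(cl, function(p) {
      x <- p$x; y <- p$y; n <- length(x); j <- c(2:n, 1L)
      abs(sum(x * y[j] - x[j] * y)) / 2
    }, numeric(1))
    best <- cl[[which.max(areas)]]
    poly <- contour(best$x, best$y, closed = TRUE,
                    pixel_size = cell$pixel_size, validate = FALSE)
  }
  cen <- colMeans(poly$vertices)
  ev <- wound_edge$vertices
  if (as_contour(wound_edge)$closed) ev <- rbind(ev, ev[1L, ])
  mid <- (ev[-nrow(ev), , drop = FALSE] + ev[-1L, , drop = FALSE]) / 2
  near <- which.min((mid[, 1] - cen[1])^2 + (mid[, 2] - cen[2])^2)
  tang <- ev[near + 1L, ] - ev[near, ]
  structure(list(polygon = poly, d_front = d_front, cell_id = cell$id,
                 tangent_deg = fold_angle_90(rad2deg(atan2(tang[2], tang[1])))),
            class = "front_roi")
}

#' @export
print.front_roi <- function(x, ...) {
  cat(sprintf("<front_roi> d_front=%g um, area=%.3f um^2, tangent=%.1f deg\n",
              x$d_front, contour_area(x$polygon), x$tangent_deg))
  invisible(x)
}

#' Rasterize a contour or front ROI onto an image grid
#'
#' @param roi A closed [contour()] or [front_roi()].
#' @param dim Image dimensions `c(nx, ny)` (pixels).
#' @param pixel_size Micrometres per pixel.
#' @return Logical matrix (`nx` x `ny`), `TRUE` where pixel centers fall
#'   inside the region.
#' @export
rasterize_roi <- function(roi, dim, pixel_size) {
  ct <- if (inherits(roi, "front_roi")) roi$polygon else as_contour(roi)
  nx <- dim[1]; ny <- dim[2]
  px <- ((seq_len(nx)) - 0.5) * pixel_size
  py <- ((seq_len(ny)) - 0.5) * pixel_size
  pts <- cbind(rep(px, times = ny), rep(py, each = nx))
  matrix(points_in_contour(pts, ct), nrow = nx)
}
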