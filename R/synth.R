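#' Specification of a synthetic curved-edge ER scene
#'
#' Describes one seeded synthetic scene: a cell abutting a wound edge of
#' prescribed signed curvature, ER rendered as thin curvilinear tubules plus
#' dense sheet regions at a prescribed front tubule fraction, paxillin-like
#' punctae with a prescribed angle distribution, and optional time-lapse
#' translation. All randomness derives from `seed`; the same spec renders
#' bit-identical outputs.
#'
#' @param seed Integer seed.
#' @param size_px Image size `c(nx, ny)` (default 256 x 256).
#' @param pixel_size Micrometres per pixel (default 0.065, a typical
#'   spinning-disk sampling).
#' @param kappa Signed edge curvature (per micrometre; positive = convex,
#'   bulging into the gap on the low-y side of the image).
#' @param f_true Target front-ROI tubule fraction in \[0, 1\].
#' @param er_density Fraction of the front ROI covered by ER (default 0.35).
#' @param tubule_width_px Tubule stroke width (default 2).
#' @param tubule_persistence Directional persistence of tubule strokes in
#'   \[0, 1\] (default 0.9; higher = straighter).
#' @param sheet_depth_um Depth of the sheet band behind the edge (default 3).
#' @param front_depth_um Depth of the front ROI used for fraction accounting
#'   (default 5).
#' @param cell_depth_um Cell depth behind the edge (default 10).
#' @param intensity Named intensities `c(cyto, tubule, sheet)`.
#' @param psf_sigma_px Gaussian PSF sigma (pixels; default 1.5; 0 disables).
#' @param poisson_scale Photon scaling for Poisson noise (0 disables).
#' @param read_noise_sd Gaussian read-noise s.d. (0 disables).
#' @param fa_n,fa_mean_deg,fa_conc Focal-adhesion count, mean angle to the
#'   edge tangent (degrees) and von Mises concentration.
#' @param n_frames,flow_um_min,frame_interval_s Time-lapse length, signed
#'   edge-normal flow speed (positive = anterograde, toward the edge) and
#'   frame interval.
#' @return An object of class `synth_spec`.
#' @seealso [synth_preset()], [make_scene()], [render_er()], [render_fa()],
#'   [render_timelapse()]
#' @export
synth_spec <- function(seed = 1L, size_px = c(256L, 256L), pixel_size = 0.065,
                       kappa = 0, f_true = 0.5, er_density = 0.35,
                       tubule_width_px = 2L, tubule_persistence = 0.9,
                       sheet_depth_um = 3, front_depth_um = 5,
                       cell_depth_um = 10,
                       intensity = c(cyto = 10, tubule = 100, sheet = 180),
                       psf_sigma_px = 1.5, poisson_scale = 2,
                       read_noise_sd = 1.5,
                       fa_n = 30L, fa_mean_deg = 80, fa_conc = 20,
                       n_frames = 10L, flow_um_min = 0.5,
                       frame_interval_s = 30) {
  if (f_true < 0 || f_true > 1) stopf("f_true must lie in [0, 1]")
  if (psf_sigma_px < 0 || read_noise_sd < 0 || poisson_scale < 0) {
    stopf("noise parameters must be >= 0")
  }
  W <- size_px[1] * pixel_size
  if (abs(kappa) > 2 / W) stopf("|kappa| too large for the image width")
  structure(as.list(environment()), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> seed=%d, %dx%d px @ %.3g um/px, kappa=%+.3g, f_true=%.2f\n",
    x$seed, x$size_px[1], x$size_px[2], x$pixel_size, x$kappa, x$f_true))
  invisible(x)
}

#' Preset scene specifications
#'
#' `"convex-default"` is a convex edge with a tubule-dominated front
#' (kappa = +0.05 per um, f_true = 0.64); `"concave-default"` a concave edge
#' with a sheet-dominated front (kappa = -0.05, f_true = 0.35) — the
#' initial-bias operating points of migrating cells at the two edge types.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synth_spec()].
#' @return A [synth_spec()].
#' @export
synth_preset <- function(name = c("convex-default", "concave-default"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  args <- if (name == "convex-default") {
    list(kappa = 0.05, f_true = 0.64, fa_mean_deg = 80)
  } else {
    list(kappa = -0.05, f_true = 0.35, fa_mean_deg = 10)
  }
  do.call(synth_spec, utils::modifyList(c(list(seed = seed), args), list(...)))
}

# wound-edge arc and scene frame ---------------------------------------------
# the gap is on the low-y side; the edge crosses the image at y_edge

synth_y_edge <- function(spec) {
  0.3 * spec$size_px[2] * spec$pixel_size
}

# edge y(x) for the arc of signed curvature kappa through (W/2, y_edge)
synth_edge_y <- function(spec, x) {
  W <- spec$size_px[1] * spec$pixel_size
  y_edge <- synth_y_edge(spec)
  k <- spec$kappa
  if (abs(k) < 1e-12) return(rep(y_edge, length(x)))
  R <- 1 / abs(k)
  dx <- x - W / 2
  sag <- R - sqrt(pmax(R^2 - dx^2, 0))
  if (k > 0) y_edge + sag - (R - sqrt(R^2 - (W / 2)^2)) / 2 else
    y_edge - sag + (R - sqrt(R^2 - (W / 2)^2)) / 2
}

#' Build the cell outline and wound edge of a synthetic scene
#'
#' The wound edge is an arc of the requested signed curvature spanning the
#' image width (gap above, monolayer below in the y-down frame); the cell is
#' a polygon whose top boundary coincides with the edge, guaranteeing a
#' perimeter contact fraction above 0.2.
#'
#' @param spec A [synth_spec()].
#' @return A list with `cell` and `wound_edge` ([contour()] objects) and
#'   `gap_probe`, a point inside the cell-free gap.
#' @export
make_scene <- function(spec) {
  W <- spec$size_px[1] * spec$pixel_size
  H <- spec$size_px[2] * spec$pixel_size
  xs <- seq(0.08 * W, 0.92 * W, length.out = 81L)
  ys <- synth_edge_y(spec, xs)
  if (any(ys < 0.05 * H) || any(ys > 0.95 * H)) {
    stopf("edge arc exceeds the image frame")
  }
  edge_x <- seq(0, W, length.out = 101L)
  wound_edge <- contour(edge_x, synth_edge_y(spec, edge_x), closed = FALSE,
                        pixel_size = spec$pixel_size, id = "wound_edge")
  y_bot <- pmin(ys + spec$cell_depth_um, 0.97 * H)
  cell <- contour(c(xs, rev(xs)), c(ys, rev(y_bot)), closed = TRUE,
                  pixel_size = spec$pixel_size, id = "cell")
  list(cell = cell, wound_edge = wound_edge,
       gap_probe = c(W / 2, max(min(ys) / 2, 0.01 * H)))
}

# pixel-grid helpers; matrices are [x, y]
synth_grids <- function(spec) {
  nx <- spec$size_px[1]; ny <- spec$size_px[2]
  px <- spec$pixel_size
  X <- matrix((seq_len(nx) - 0.5) * px, nx, ny)
  Y <- matrix((seq_len(ny) - 0.5) * px, nx, ny, byrow = TRUE)
  list(X = X, Y = Y)
}

# depth below the local edge (um); negative above the edge (in the gap)
synth_depth <- function(spec, g) {
  edge_y <- matrix(synth_edge_y(spec, g$X[, 1]), nrow(g$X), ncol(g$X))
  g$Y - edge_y
}

#' Render the ER channel of a synthetic scene with ground truth
#'
#' Sheets are drawn as a thresholded smooth random field in the band behind
#' the edge; tubules as persistent random curvilinear strokes through the
#' cell. Stroke addition is steered by area accounting so the realized
#' front-ROI tubule fraction lands within 0.02 of `f_true`. The composited
#' intensities are PSF-blurred and carry Poisson plus Gaussian read noise;
#' the ground-truth mask reflects the pre-noise geometry.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `synth_er_scene`: `image` ([er_image()]),
#'   `mask` ([class_mask()]), `truth` (list with `f_true_requested`,
#'   `f_realized` in the front ROI, `front_roi` logical matrix, `cell_mask`,
#'   plus the scene contours).
#' @export
render_er <- function(spec) {
  with_seed(spec$seed, render_er_impl(spec))
}

render_er_impl <- function(spec) {
  scene <- make_scene(spec)
  g <- synth_grids(spec)
  nx <- spec$size_px[1]; ny <- spec$size_px[2]
  px <- spec$pixel_size
  depth <- synth_depth(spec, g)
  cell <- rasterize_roi(scene$cell, c(nx, ny), px)
  front <- cell & depth >= 0 & depth <= spec$front_depth_um
  n_roi <- sum(front)
  if (n_roi == 0) stopf("front ROI is empty; check geometry")
  er_target <- spec$er_density * n_roi
  sheet_target <- round((1 - spec$f_true) * er_target)
  tub_target <- round(spec$f_true * er_target)
  mask <- matrix(0L, nx, ny)
  # sheets: smooth random field, thresholded within the sheet band to the
  # target area
  if (sheet_target > 0) {
    band <- cell & depth >= 0 & depth <= spec$sheet_depth_um
    if (!any(band)) stopf("infeasible f_true: sheet band empty")
    field <- matrix(stats::rnorm(nx * ny), nx, ny)
    field <- gauss_smooth(field, 6)
    q <- stats::quantile(field[band & front], 1 - sheet_target / sum(band & front))
    mask[band & field >= q] <- 2L
  }
  # tubules: persistent random strokes, added until the front-ROI tubule
  # area reaches the target; the final stroke is truncated pixel-wise
  tub_now <- 0L
  guard <- 0L
  while (tub_now < tub_target && guard < 4000L) {
    guard <- guard + 1L
    stroke <- tubule_stroke(spec, cell, depth)
    new <- stroke & mask == 0L & cell
    gain <- sum(new & front)
    if (gain == 0) next
    if (tub_now + gain > tub_target + 0.01 * er_target) {
      idx <- which(new & front)
      take <- tub_target - tub_now
      mask[idx[seq_len(max(take, 0L))]] <- 1L
      new_out <- new & !front
      mask[new_out] <- 1L
      tub_now <- tub_now + max(take, 0L)
    } else {
      mask[new] <- 1L
      tub_now <- tub_now + gain
    }
  }
  if (spec$f_true > 0 && tub_now == 0L) stopf("failed to draw any tubules")
  f_realized <- if (tub_now + sum(mask == 2L & front) == 0) NA_real_ else
    sum(mask == 1L & front) / sum(mask != 0L & front)
  img <- matrix(0, nx, ny)
  img[cell] <- spec$intensity[["cyto"]]
  img[mask == 1L] <- spec$intensity[["tubule"]]
  img[mask == 2L] <- spec$intensity[["sheet"]]
  img <- synth_apply_noise(spec, img)
  list(image = er_image(img, px, channel = "ER"),
       mask = class_mask(mask, px, model_hash = "ground_truth"),
       truth = list(f_true_requested = spec$f_true, f_realized = f_realized,
                    front_roi = front, cell_mask = cell,
                    cell = scene$cell, wound_edge = scene$wound_edge,
                    gap_probe = scene$gap_probe)) |>
    structure(class = "synth_er_scene")
}

synth_apply_noise <- function(spec, img) {
  nx <- nrow(img); ny <- ncol(img)
  if (spec$psf_sigma_px > 0) img <- gauss_smooth(img, spec$psf_sigma_px)
  if (spec$poisson_scale > 0) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0) * spec$poisson_scale),
                  nx, ny) / spec$poisson_scale
  }
  if (spec$read_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$read_noise_sd), nx, ny)
  }
  pmax(img, 0)
}

# persistent random-walk stroke through the cell, painted at tubule width
tubule_stroke <- function(spec, cell, depth) {
  nx <- nrow(cell); ny <- ncol(cell)
  idx_cell <- which(cell)
  start <- idx_cell[sample.int(length(idx_cell), 1L)]
  x <- ((start - 1L) %% nx) + 1L
  y <- ((start - 1L) %/% nx) + 1L
  th <- stats::runif(1, 0, 2 * pi)
  sd_turn <- (1 - spec$tubule_persistence) * 1.2 + 0.05
  n_steps <- round(stats::runif(1, 60, 220))
  pts <- matrix(0L, n_steps, 2)
  n_ok <- 0L
  for (i in seq_len(n_steps)) {
    th <- th + stats::rnorm(1, 0, sd_turn)
    x <- x + cos(th); y <- y + sin(th)
    xi <- round(x); yi <- round(y)
    if (xi < 1 || xi > nx || yi < 1 || yi > ny || !cell[xi, yi]) break
    n_ok <- n_ok + 1L
    pts[n_ok, ] <- c(xi, yi)
  }
  stroke <- matrix(FALSE, nx, ny)
  if (n_ok == 0L) return(stroke)
  pts <- pts[seq_len(n_ok), , drop = FALSE]
  r <- (spec$tubule_width_px - 1) / 2
  offs <- expand.grid(dx = seq(-ceiling(r), ceiling(r)),
                      dy = seq(-ceiling(r), ceiling(r)))
  offs <- offs[offs$dx^2 + offs$dy^2 <= max(r, 0.5)^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    xs <- pts[, 1] + offs$dx[k]; ys <- pts[, 2] + offs$dy[k]
    ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    stroke[cbind(xs[ok], ys[ok])] <- TRUE
  }
  stroke
}

#' Render the focal-adhesion channel of a synthetic scene
#'
#' Elliptical punctae in the front band; each ellipse's long axis makes an
#' angle with the local edge tangent drawn from a von Mises distribution
#' (axial; concentration 0 = uniform). Optionally, centers are constrained
#' onto tubule or sheet regions of a supplied ER mask for association tests.
#'
#' @param spec A [synth_spec()].
#' @param place_on Optional: `"tubule"` or `"sheet"` with `er_mask` to
#'   constrain FA centers onto that ER class.
#' @param er_mask Optional [class_mask()] used with `place_on`.
#' @return A list of class `synth_fa_scene`: `image`, `truth` (data frame
#'   with per-FA `x_um`, `y_um`, `angle_deg` in \[0, 90\], `class`), and the
#'   scene contours.
#' @export
render_fa <- function(spec, place_on = NULL, er_mask = NULL) {
  with_seed(spec$seed + 1000L, render_fa_impl(spec, place_on, er_mask))
}

render_fa_impl <- function(spec, place_on, er_mask) {
  scene <- make_scene(spec)
  g <- synth_grids(spec)
  nx <- spec$size_px[1]; ny <- spec$size_px[2]
  px <- spec$pixel_size
  depth <- synth_depth(spec, g)
  cell <- rasterize_roi(scene$cell, c(nx, ny), px)
  zone <- cell & depth >= 0.3 & depth <= spec$front_depth_um
  if (!is.null(place_on)) {
    if (is.null(er_mask)) stopf("place_on requires er_mask")
    code <- if (place_on == "tubule") 1L else 2L
    zone <- zone & er_mask$data == code
  }
  idx <- which(zone)
  a_px <- 1.1 / px / 2; b_px <- 0.35 / px / 2  # ellipse semi-axes
  need_area <- spec$fa_n * pi * a_px * b_px * 2.5
  if (length(idx) < need_area) stopf("FA count exceeds placeable area")
  # punctae are discrete: place centers with a minimum separation so
  # neighbouring ellipses do not merge into one detected object
  min_sep2 <- (1.6 * a_px)^2
  cx <- cy <- integer(0)
  cand <- idx[sample.int(length(idx))]
  for (cc in cand) {
    if (length(cx) >= spec$fa_n) break
    x0 <- ((cc - 1L) %% nx) + 1L
    y0 <- ((cc - 1L) %/% nx) + 1L
    if (length(cx) && any((cx - x0)^2 + (cy - y0)^2 < min_sep2)) next
    cx <- c(cx, x0); cy <- c(cy, y0)
  }
  if (length(cx) < spec$fa_n) stopf("FA count exceeds placeable area")
  tang <- rad2deg(atan2(
    synth_edge_y(spec, (cx - 0.5) * px + 0.5) -
      synth_edge_y(spec, (cx - 0.5) * px - 0.5), 1))
  dev <- rvonmises_axial(spec$fa_n, spec$fa_mean_deg, spec$fa_conc)
  th_img <- tang + dev  # ellipse axis angle in image frame
  img <- matrix(0, nx, ny)
  for (i in seq_len(spec$fa_n)) {
    t <- deg2rad(th_img[i])
    rx <- ceiling(a_px) + 1L
    xr <- max(1L, cx[i] - rx):min(nx, cx[i] + rx)
    yr <- max(1L, cy[i] - rx):min(ny, cy[i] + rx)
    dx <- outer(xr - cx[i], rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - cy[i])
    u <- dx * cos(t) + dy * sin(t)
    v <- -dx * sin(t) + dy * cos(t)
    inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
    img[xr, yr][inside] <- 150
  }
  img <- synth_apply_noise(spec, img)
  ang <- fold_angle_90(dev)
  truth <- data.frame(x_um = (cx - 0.5) * px, y_um = (cy - 0.5) * px,
                      angle_deg = ang, class = classify_fa(ang))
  structure(list(image = er_image(img, px, channel = "FA"), truth = truth,
                 cell = scene$cell, wound_edge = scene$wound_edge),
            class = "synth_fa_scene")
}

# axial von Mises sample (degrees, deviation from the mean direction),
# Best-Fisher rejection sampling on the doubled angle
rvonmises_axial <- function(n, mean_deg, conc) {
  if (conc <= 0) return(stats::runif(n, 0, 180))
  kk <- conc
  a <- 1 + sqrt(1 + 4 * kk^2)
  b <- (a - sqrt(2 * a)) / (2 * kk)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kk * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        th <- sign(u[3] - 0.5) * acos(f)
        out[i] <- th
        break
      }
    }
  }
  mean_deg + rad2deg(out) / 2  # halve: axial orientations live on [0, 180)
}

#' Render a time-lapse ER stack with a known flow velocity
#'
#' The pre-noise ER scene is translated along the edge normal at the
#' specified signed velocity (positive = anterograde, toward the edge);
#' noise is redrawn per frame.
#'
#' @param spec A [synth_spec()] (uses `n_frames`, `flow_um_min`,
#'   `frame_interval_s`).
#' @return A list of class `synth_timelapse`: `stack` ([er_stack()]),
#'   `flow_um_min` (the true signed speed), plus the first-frame `mask` and
#'   scene contours.
#' @export
render_timelapse <- function(spec) {
  if (spec$n_frames < 5L) stopf("time-lapse needs at least 5 frames")
  base_spec <- spec
  base_spec$poisson_scale <- 0; base_spec$read_noise_sd <- 0
  base_spec$psf_sigma_px <- 0
  scn <- render_er(base_spec)
  nx <- spec$size_px[1]; ny <- spec$size_px[2]
  px <- spec$pixel_size
  base <- matrix(0, nx, ny)
  base[scn$truth$cell_mask] <- spec$intensity[["cyto"]]
  base[scn$mask$data == 1L] <- spec$intensity[["tubule"]]
  base[scn$mask$data == 2L] <- spec$intensity[["sheet"]]
  dt_min <- spec$frame_interval_s / 60
  total_shift <- abs(spec$flow_um_min) * dt_min * (spec$n_frames - 1) / px
  if (total_shift > 0.25 * ny) stopf("velocity moves the scene out of frame")
  with_seed(spec$seed + 2000L, {
    frames <- array(0, c(nx, ny, spec$n_frames))
    for (tt in seq_len(spec$n_frames)) {
      # positive flow moves signal toward the edge (decreasing y)
      dy <- -spec$flow_um_min * dt_min * (tt - 1) / px
      fr <- shift_bilinear(base, 0, dy)
      if (spec$psf_sigma_px > 0) fr <- gauss_smooth(fr, spec$psf_sigma_px)
      if (spec$poisson_scale > 0) {
        fr <- matrix(stats::rpois(length(fr), pmax(fr, 0) * spec$poisson_scale),
                     nx, ny) / spec$poisson_scale
      }
      if (spec$read_noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(length(fr), 0, spec$read_noise_sd), nx, ny)
      }
      frames[, , tt] <- pmax(fr, 0)
    }
    structure(list(stack = er_stack(frames, px, spec$frame_interval_s),
                   flow_um_min = spec$flow_um_min, mask = scn$mask,
                   cell = scn$truth$cell, wound_edge = scn$truth$wound_edge),
              class = "synth_timelapse")
  })
}

shift_bilinear <- function(img, dx, dy) {
  nx <- nrow(img); ny <- ncol(img)
  xs <- matrix(seq_len(nx) - dx, nx, ny)
  ys <- matrix(seq_len(ny) - dy, nx, ny, byrow = TRUE)
  out <- matrix(0, nx, ny)
  ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
  out[ok] <- bilinear_sample(img, xs[ok], ys[ok])
  out
}

#' Render a scene with a component concentrated at the edge or cell center
#'
#' Produces an intensity image whose signal is a blurred blob either hugging
#' the wound edge or sitting at the cell centroid — the two poles of the
#' mean-distribution-from-edge (MDE) readout.
#'
#' @param spec A [synth_spec()].
#' @param where `"edge"` or `"center"`.
#' @return A list with `image`, `cell_mask`, and the scene contours.
#' @export
render_polarized <- function(spec, where = c("edge", "center")) {
  where <- match.arg(where)
  with_seed(spec$seed + 3000L, {
    scene <- make_scene(spec)
    g <- synth_grids(spec)
    nx <- spec$size_px[1]; ny <- spec$size_px[2]
    px <- spec$pixel_size
    depth <- synth_depth(spec, g)
    cell <- rasterize_roi(scene$cell, c(nx, ny), px)
    img <- matrix(0, nx, ny)
    if (where == "edge") {
      img[cell & depth >= 0 & depth <= 2] <- 100
    } else {
      cen_d <- spec$cell_depth_um / 2
      img[cell & abs(depth - cen_d) <= 1.5] <- 100
    }
    img <- synth_apply_noise(spec, img)
    list(image = er_image(img, px), cell_mask = cell,
         cell = scene$cell, wound_edge = scene$wound_edge)
  })
}

#' Sample a balanced labeled-pixel training set from synthetic scenes
#'
#' Draws equal numbers of tubule, sheet and background pixels from the
#' ground-truth masks of one or more rendered scenes — the synthetic
#' stand-in for interactively marked training regions.
#'
#' Tubule and sheet pixels are sampled uniformly from their classes; the
#' background class is emphasized (`background_multiplier` times more
#' pixels, `halo_fraction` of them from the blurred halo just outside ER
#' structures). This weighting places the learned class boundary at the
#' geometric structure outline rather than the point-spread halo, which
#' would otherwise inflate tubule areas — the synthetic counterpart of
#' iteratively refining interactive training until the segmentation matches
#' the image.
#'
#' @param specs A [synth_spec()] or list of specs.
#' @param n_per_class Pixels per ER class across scenes (default 1000).
#' @param seed Sampling seed.
#' @param background_multiplier Background pixels relative to `n_per_class`
#'   (default 4).
#' @param halo_fraction Fraction of background pixels drawn from within
#'   `halo_brush` pixels of an ER structure (default 0.6).
#' @param halo_brush Diameter (px) of the halo dilation brush (default 7).
#' @return An object of class `er_training_set`: list of `scenes` (rendered
#'   [render_er()] outputs) and `labels` (per scene, a data frame with `idx`
#'   and `class` in 1:3).
#' @export
make_training_set <- function(specs, n_per_class = 1000L, seed = 1L,
                              background_multiplier = 4,
                              halo_fraction = 0.6, halo_brush = 7L) {
  if (inherits(specs, "synth_spec")) specs <- list(specs)
  scenes <- lapply(specs, render_er)
  with_seed(seed, {
    labels <- vector("list", length(scenes))
    for (cls in 1:3) {
      avail <- lapply(scenes, function(s) {
        m <- s$mask$data
        if (cls == 1L) return(which(m == 1L))
        if (cls == 2L) return(which(m == 2L))
        er <- EBImage::dilate(EBImage::Image((m != 0L) * 1),
                              EBImage::makeBrush(as.integer(halo_brush), "disc"))
        halo <- which(m == 0L & as.matrix(er) > 0)
        far <- which(m == 0L & as.matrix(er) == 0)
        list(halo = halo, far = far)
      })
      if (cls == 3L) {
        halos <- lapply(avail, `[[`, "halo")
        fars <- lapply(avail, `[[`, "far")
        n_bg <- round(n_per_class * background_multiplier)
        qh <- distribute_quota(lengths(halos), round(n_bg * halo_fraction))
        qf <- distribute_quota(lengths(fars), n_bg - sum(qh))
        for (i in seq_along(scenes)) {
          take <- c(
            if (qh[i] > 0L) halos[[i]][sample.int(length(halos[[i]]), qh[i])],
            if (qf[i] > 0L) fars[[i]][sample.int(length(fars[[i]]), qf[i])])
          if (length(take)) {
            labels[[i]] <- rbind(labels[[i]],
                                 data.frame(idx = take, class = cls))
          }
        }
        next
      }
      n_tot <- sum(lengths(avail))
      if (n_tot == 0L) {
        stopf("no pixels available for class: %s", ER_CLASSES[cls])
      }
      quota <- distribute_quota(lengths(avail), n_per_class)
      for (i in seq_along(scenes)) {
        if (quota[i] == 0L) next
        take <- avail[[i]][sample.int(length(avail[[i]]), quota[i])]
        labels[[i]] <- rbind(labels[[i]],
                             data.frame(idx = take, class = cls))
      }
    }
    structure(list(scenes = scenes, labels = labels),
              class = "er_training_set")
  })
}

distribute_quota <- function(sizes, total) {
  q <- pmin(sizes, ceiling(total * sizes / sum(sizes)))
  # trim overshoot deterministically from the largest pools
  while (sum(q) > total) {
    i <- which.max(q)
    q[i] <- q[i] - (sum(q) - total)
    q[i] <- max(q[i], 0L)
  }
  as.integer(q)
}

#' Train an ER classifier from a synthetic training set
#'
#' Computes feature stacks for each scene of an [make_training_set()] result
#' and fits one [train_classifier()] ensemble on the pooled labeled pixels.
#'
#' @param tset An `er_training_set`.
#' @param scales,membrane_size,n_orient Feature parameters
#'   (see [compute_features()]).
#' @param n_trees,seed Ensemble parameters (see [train_classifier()]).
#' @return An `er_classifier`.
#' @export
train_on_synthetic <- function(tset, scales = c(1, 2, 4, 8),
                               membrane_size = 19L, n_orient = 30L,
                               n_trees = 100L, seed = 1L) {
  if (!inherits(tset, "er_training_set")) stopf("tset must be an er_training_set")
  fms <- list(); cls <- list()
  stack1 <- NULL
  for (i in seq_along(tset$scenes)) {
    lab <- tset$labels[[i]]
    if (is.null(lab) || !nrow(lab)) next
    st <- compute_features(tset$scenes[[i]]$image, scales = scales,
                           membrane_size = membrane_size, n_orient = n_orient)
    if (is.null(stack1)) stack1 <- st
    fms[[length(fms) + 1L]] <- feature_matrix(st, lab$idx)
    cls[[length(cls) + 1L]] <- lab$class
  }
  fm <- do.call(rbind, fms)
  df <- as.data.frame(fm)
  df$.class <- factor(ER_CLASSES[unlist(cls)], levels = ER_CLASSES)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, mtry = floor(sqrt(ncol(fm))),
    probability = TRUE, seed = as.integer(seed), num.threads = 1L)
  oob_pred <- max.col(fit$predictions, ties.method = "first")
  structure(list(forest = fit, classes = ER_CLASSES,
                 config = stack1$config, feature_hash = stack1$hash,
                 seed = as.integer(seed), n_trees = as.integer(n_trees),
                 oob_accuracy = mean(ER_CLASSES[oob_pred] == df$.class)),
            class = "er_classifier")
}
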