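#' Orientation histogram by the Fourier-components method
#'
#' Quantifies the preferred orientation of image structures from the 2D power
#' spectrum: the image region is Hann-windowed, Fourier-transformed, and the
#' spectral energy is binned by spatial-frequency angle (a structure at
#' orientation theta concentrates spectral energy at theta + 90 degrees).
#' Focal-adhesion analyses use 6 bins on \[0, 90\] degrees; microtubule
#' analyses use 10 bins on \[0, 180\].
#'
#' @param img An [er_image()] or matrix (the cropped ROI; >= 32 x 32 px).
#' @param n_bins Number of histogram bins (default 6).
#' @param angle_range `c(0, 90)` (axial, folded) or `c(0, 180)`.
#' @param edge_tangent_deg Optional local wound-edge tangent (degrees); when
#'   supplied, angles are reported relative to it.
#' @return A data frame of class `orientation_histogram` with columns
#'   `bin_lo`, `bin_hi` (degrees) and `weight` (normalized to sum 1).
#' @export
directionality_fourier <- function(img, n_bins = 6L, angle_range = c(0, 90),
                                   edge_tangent_deg = NULL) {
  x <- if (inherits(img, "er_image")) img$data else as.matrix(img)
  if (min(dim(x)) < 32L) stopf("ROI too small (min 32 x 32 px)")
  nx <- nrow(x); ny <- ncol(x)
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nx) - 1) / (nx - 1)))
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(ny) - 1) / (ny - 1)))
  xw <- (x - mean(x)) * outer(wx, wy)
  P <- Mod(stats::fft(xw))^2
  fx <- ifelse(seq_len(nx) - 1 <= nx / 2, seq_len(nx) - 1, seq_len(nx) - 1 - nx)
  fy <- ifelse(seq_len(ny) - 1 <= ny / 2, seq_len(ny) - 1, seq_len(ny) - 1 - ny)
  FX <- matrix(fx, nx, ny); FY <- matrix(fy, nx, ny, byrow = TRUE)
  keep <- (FX != 0 | FY != 0)
  # structure orientation is perpendicular to the spectral direction;
  # y-down image frame
  ang <- rad2deg(atan2(FY[keep], FX[keep])) + 90
  if (!is.null(edge_tangent_deg)) ang <- ang - edge_tangent_deg
  span <- diff(angle_range)
  ang <- if (span == 90) fold_angle_90(ang) else ang %% 180
  w <- P[keep]
  br <- seq(angle_range[1], angle_range[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(ang, br, rightmost.closed = TRUE), 1L), n_bins)
  wt <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  wt <- wt / sum(wt)
  out <- data.frame(bin_lo = br[-length(br)], bin_hi = br[-1], weight = wt)
  class(out) <- c("orientation_histogram", "data.frame")
  out
}

#' Detect focal adhesions in a paxillin-like channel
#'
#' Background-subtracted thresholding (Otsu by default), connected
#' components, a minimum-area filter, and per-object orientation from second
#' central moments (ellipse major axis). When a wound edge is supplied the
#' angle is reported relative to the local edge tangent, folded to
#' \[0, 90\] degrees, and each object is classified with [classify_fa()].
#'
#' @param img An [er_image()] of the FA channel.
#' @param cell_mask Optional region restriction (logical matrix or contour).
#' @param wound_edge Optional [contour()] of the wound edge.
#' @param threshold `"otsu"` or a numeric intensity threshold applied after
#'   background subtraction.
#' @param min_area_um2 Minimum object area (default 0.1 square micrometres).
#' @return A data frame of class `fa_table`, one row per FA: `fa_id`, `x_um`,
#'   `y_um`, `area_um2`, `angle_deg` (to the edge tangent if given, else to
#'   the image x axis), `class`. An empty image yields an empty table.
#' @export
detect_fa <- function(img, cell_mask = NULL, wound_edge = NULL,
                      threshold = "otsu", min_area_um2 = 0.1) {
  img <- as_er_image(img)
  px <- img$pixel_size
  x <- img$data
  cm <- if (is.null(cell_mask)) matrix(TRUE, nrow(x), ncol(x)) else
    roi_selector(cell_mask, dim(x), px)
  bg <- if (any(!cm)) stats::median(x[!cm]) else stats::median(x)
  xs <- pmax(x - bg, 0)
  empty <- data.frame(fa_id = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), angle_deg = numeric(),
                      class = character())
  class(empty) <- c("fa_table", "data.frame")
  if (max(xs) <= 0) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(xs)
    EBImage::otsu(EBImage::Image((xs - rng[1]) / diff(rng)), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else as.numeric(threshold)
  bw <- (xs > thr) & cm
  if (!any(bw)) return(empty)
  lbl <- EBImage::bwlabel(EBImage::Image(bw * 1))
  n_obj <- max(lbl)
  if (n_obj == 0) return(empty)
  idx <- which(as.matrix(lbl) > 0, arr.ind = TRUE)
  grp <- as.matrix(lbl)[as.matrix(lbl) > 0]
  rows <- lapply(seq_len(n_obj), function(k) {
    pxl <- idx[grp == k, , drop = FALSE]
    a <- nrow(pxl) * px^2
    if (a < min_area_um2) return(NULL)
    cx <- mean(pxl[, 1]); cy <- mean(pxl[, 2])
    mxx <- mean((pxl[, 1] - cx)^2); myy <- mean((pxl[, 2] - cy)^2)
    mxy <- mean((pxl[, 1] - cx) * (pxl[, 2] - cy))
    theta <- rad2deg(0.5 * atan2(2 * mxy, mxx - myy))
    data.frame(x_um = (cx - 0.5) * px, y_um = (cy - 0.5) * px,
               area_um2 = a, theta = theta)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  if (!is.null(wound_edge)) {
    ref <- local_edge_tangent(wound_edge, cbind(rows$x_um, rows$y_um))
    ang <- fold_angle_90(rows$theta - ref)
  } else {
    ang <- fold_angle_90(rows$theta)
  }
  out <- data.frame(fa_id = seq_len(nrow(rows)), x_um = rows$x_um,
                    y_um = rows$y_um, area_um2 = rows$area_um2,
                    angle_deg = ang, class = classify_fa(ang))
  class(out) <- c("fa_table", "data.frame")
  out
}

# tangent angle (deg) of the edge polyline at the point nearest each query
local_edge_tangent <- function(edge, pts) {
  edge <- as_contour(edge, closed = FALSE)
  v <- edge$vertices
  if (edge$closed) v <- rbind(v, v[1L, ])
  mid <- (v[-nrow(v), , drop = FALSE] + v[-1L, , drop = FALSE]) / 2
  seg <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
  vapply(seq_len(nrow(pts)), function(i) {
    k <- which.min((mid[, 1] - pts[i, 1])^2 + (mid[, 2] - pts[i, 2])^2)
    rad2deg(atan2(seg[k, 2], seg[k, 1]))
  }, numeric(1))
}

#' Classify a focal adhesion by its angle to the wound edge
#'
#' Angles between 0 and 18 degrees (inclusive) are parallel to the wound,
#' between 72 and 90 degrees (inclusive) perpendicular; anything else is
#' excluded from orientation statistics.
#'
#' @param angle_to_edge Angle(s) in degrees, in \[0, 90\].
#' @return Character vector: `"parallel"`, `"perpendicular"` or `"excluded"`.
#' @export
#' @examples
#' classify_fa(c(10, 45, 80))
classify_fa <- function(angle_to_edge) {
  if (any(angle_to_edge < 0 | angle_to_edge > 90)) {
    stopf("angle_to_edge must lie in [0, 90] degrees")
  }
  ifelse(angle_to_edge <= 18, "parallel",
         ifelse(angle_to_edge >= 72, "perpendicular", "excluded"))
}

#' Associate focal adhesions with ER classes
#'
#' For each FA, finds the majority ER class (tubule or sheet) within
#' `contact_radius` of the FA centroid footprint; FAs with no ER pixel within
#' reach get `"none"`. Also summarizes, per FA class, the fraction of FAs
#' contacting tubules and sheets.
#'
#' @param fas An `fa_table` from [detect_fa()].
#' @param ermask A [class_mask()] co-registered with the FA image.
#' @param contact_radius Contact distance in micrometres (default 0.3).
#' @return A list with `fas` (the table plus an `er_contact` column) and
#'   `summary` (per FA class: `frac_tubule`, `frac_sheet`, `n`).
#' @export
fa_er_association <- function(fas, ermask, contact_radius = 0.3) {
  if (contact_radius < 0) stopf("contact_radius must be >= 0")
  if (!inherits(ermask, "class_mask")) stopf("ermask must be a class_mask")
  px <- ermask$pixel_size
  r_px <- contact_radius / px
  dm <- dim(ermask$data)
  contact <- character(nrow(fas))
  for (i in seq_len(nrow(fas))) {
    cx <- fas$x_um[i] / px + 0.5; cy <- fas$y_um[i] / px + 0.5
    xr <- max(1, floor(cx - r_px)):min(dm[1], ceiling(cx + r_px))
    yr <- max(1, floor(cy - r_px)):min(dm[2], ceiling(cy + r_px))
    sub <- ermask$data[xr, yr, drop = FALSE]
    dx <- outer(xr - cx, rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - cy)
    sel <- (dx^2 + dy^2) <= r_px^2
    vals <- sub[sel & sub != 0L]
    contact[i] <- if (!length(vals)) "none" else
      c("tubule", "sheet")[which.max(tabulate(vals, nbins = 2L))]
  }
  fas$er_contact <- contact
  summ <- do.call(rbind, lapply(split(fas, fas$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d),
               frac_tubule = mean(d$er_contact == "tubule"),
               frac_sheet = mean(d$er_contact == "sheet"))
  }))
  rownames(summ) <- NULL
  list(fas = fas, summary = summ)
}
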