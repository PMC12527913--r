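#' Calibrated time-lapse stack
#'
#' @param data 3D numeric array `[x, y, t]` of intensities.
#' @param pixel_size Micrometres per pixel.
#' @param frame_interval_s Seconds between frames.
#' @return An object of class `er_stack`.
#' @export
er_stack <- function(data, pixel_size, frame_interval_s) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stopf("stack must be a 3D array [x, y, t]")
  if (pixel_size <= 0 || frame_interval_s <= 0) {
    stopf("pixel_size and frame_interval_s must be > 0")
  }
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval_s = frame_interval_s),
            class = "er_stack")
}

#' @export
print.er_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<er_stack> %d x %d px, %d frames, %.4g um/px, dt %.3g s\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval_s))
  invisible(x)
}

#' Extract a kymograph along a line
#'
#' Samples the intensity along a line segment in every frame (bilinear
#' interpolation, averaged across a perpendicular width) and stacks the
#' profiles into a space x time map. Orient the line so that its second
#' endpoint points toward the wound edge: increasing space index then means
#' "toward the edge", and a positive flow speed is anterograde.
#'
#' @param stack An [er_stack()] with >= 5 frames.
#' @param line 2 x 2 matrix: rows are the start and end points (micrometres),
#'   the end point on the wound-edge side.
#' @param width_px Averaging width perpendicular to the line (default 3).
#' @return An object of class `kymograph`: `data` (space x time),
#'   `space_step_um`, `frame_interval_s`, `line`.
#' @export
kymograph <- function(stack, line, width_px = 3L) {
  if (!inherits(stack, "er_stack")) stopf("stack must be an er_stack")
  d <- dim(stack$data)
  if (d[3] < 5L) stopf("kymograph needs at least 5 frames")
  line <- matrix(as.numeric(line), 2, 2)
  px <- stack$pixel_size
  p0 <- line[1, ] / px + 0.5; p1 <- line[2, ] / px + 0.5
  len <- sqrt(sum((p1 - p0)^2))
  n_s <- max(2L, floor(len)) + 1L
  tvec <- seq(0, 1, length.out = n_s)
  dir <- (p1 - p0) / len
  nrm <- c(-dir[2], dir[1])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  xs <- outer(p0[1] + tvec * (p1[1] - p0[1]), offs * nrm[1], "+")
  ys <- outer(p0[2] + tvec * (p1[2] - p0[2]), offs * nrm[2], "+")
  if (min(xs) < 1 || max(xs) > d[1] || min(ys) < 1 || max(ys) > d[2]) {
    stopf("kymograph line (with width) exits the image")
  }
  kdat <- matrix(0, n_s, d[3])
  for (tt in seq_len(d[3])) {
    fr <- stack$data[, , tt]
    kdat[, tt] <- rowMeans(matrix(bilinear_sample(fr, xs, ys), n_s))
  }
  structure(list(data = kdat, space_step_um = len * px / (n_s - 1L),
                 frame_interval_s = stack$frame_interval_s, line = line),
            class = "kymograph")
}

bilinear_sample <- function(img, x, y) {
  x0 <- as.vector(pmin(pmax(floor(x), 1), nrow(img) - 1L))
  y0 <- as.vector(pmin(pmax(floor(y), 1), ncol(img) - 1L))
  fx <- as.vector(x) - x0; fy <- as.vector(y) - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kymograph> %d positions x %d frames, %.3g um/step\n",
              d[1], d[2], x$space_step_um))
  invisible(x)
}

#' Dominant flow direction and speed from a kymograph
#'
#' Radon-style slope search: each candidate velocity shears the
#' (column-mean-subtracted) kymograph so that structures moving at that
#' velocity become horizontal; the velocity maximizing the variance of the
#' time-averaged sheared profile is the dominant slope. Positive velocity
#' (toward the edge) is anterograde, negative retrograde; speeds below
#' `speed_floor` are reported as no net flow.
#'
#' @param k A [kymograph()].
#' @param speed_floor Minimum speed for a direction call
#'   (micrometres/minute; default 0.05).
#' @param v_max Largest speed searched (default: one kymograph length per
#'   stack duration).
#' @return A list with `direction` (`"anterograde"`, `"retrograde"` or
#'   `"none"`) and `speed_um_min` (unsigned).
#' @export
flow_direction <- function(k, speed_floor = 0.05, v_max = NULL) {
  if (!inherits(k, "kymograph")) stopf("k must be a kymograph")
  kd <- k$data
  n_s <- nrow(kd); n_t <- ncol(kd)
  if (n_t < 5L) stopf("kymograph needs at least 5 time points")
  kd <- kd - matrix(colMeans(kd), n_s, n_t, byrow = TRUE)
  if (max(abs(kd)) < 1e-12) {
    return(list(direction = "none", speed_um_min = 0))
  }
  dt_min <- k$frame_interval_s / 60
  ds <- k$space_step_um
  v_max <- v_max %||% (n_s * ds / (n_t * dt_min))
  vgrid <- seq(-v_max, v_max, length.out = 201L)
  score <- vapply(vgrid, function(v) shear_score(kd, v * dt_min / ds), numeric(1))
  b <- which.max(score)
  # parabolic refinement around the best grid point
  v_best <- vgrid[b]
  if (b > 1L && b < length(vgrid)) {
    y1 <- score[b - 1L]; y2 <- score[b]; y3 <- score[b + 1L]
    den <- (y1 - 2 * y2 + y3)
    if (abs(den) > 0) {
      v_best <- vgrid[b] + 0.5 * (y1 - y3) / den * (vgrid[2] - vgrid[1])
    }
  }
  if (abs(v_best) < speed_floor) {
    list(direction = "none", speed_um_min = 0)
  } else {
    list(direction = if (v_best > 0) "anterograde" else "retrograde",
         speed_um_min = abs(v_best))
  }
}

# variance of the time-mean profile after shearing by `slope` px/frame;
# only trajectories visible in every frame are scored, which makes the
# measure exactly symmetric under time reversal
shear_score <- function(kd, slope) {
  n_s <- nrow(kd); n_t <- ncol(kd)
  acc <- numeric(n_s); cnt <- numeric(n_s)
  xi <- seq_len(n_s)
  # shear about the middle frame: time reversal then maps the score to its
  # mirror image in the slope exactly
  for (tt in seq_len(n_t)) {
    pos <- xi + slope * (tt - (n_t + 1) / 2)
    ok <- pos >= 1 & pos <= n_s
    if (!any(ok)) next
    p0 <- floor(pos[ok]); fr <- pos[ok] - p0
    p1 <- pmin(p0 + 1L, n_s)
    val <- kd[p0, tt] * (1 - fr) + kd[p1, tt] * fr
    acc[ok] <- acc[ok] + val
    cnt[ok] <- cnt[ok] + 1
  }
  use <- cnt == n_t
  if (sum(use) < 3L) return(0)
  stats::var(acc[use] / n_t)
}

#' Tubule fraction over the frames of a time-lapse stack
#'
#' Applies [classify()] and [tubule_fraction()] frame by frame. Frames whose
#' ROI contains no ER pixels are flagged (`ok = FALSE`, `f_tubule = NA`)
#' rather than aborting the series.
#'
#' @param stack An [er_stack()].
#' @param model An [train_classifier()] model.
#' @param roi `NULL`, a single region (logical matrix / contour /
#'   [front_roi()]) applied to every frame, or a list with one region per
#'   frame.
#' @return A data frame with `frame`, `time_s`, `f_tubule`, `ok`.
#' @export
tubule_fraction_timeseries <- function(stack, model, roi = NULL) {
  if (!inherits(stack, "er_stack")) stopf("stack must be an er_stack")
  n_t <- dim(stack$data)[3]
  rois <- if (is.list(roi) && !inherits(roi, c("er_contour", "front_roi"))) {
    if (length(roi) != n_t) stopf("need one ROI per frame")
    roi
  } else rep(list(roi), n_t)
  rows <- lapply(seq_len(n_t), function(tt) {
    img <- er_image(stack$data[, , tt], stack$pixel_size, t_index = tt)
    msk <- classify(model, img)
    fr <- tryCatch(tubule_fraction(msk, rois[[tt]])$f_tubule,
                   error = function(e) NA_real_)
    data.frame(frame = tt, time_s = (tt - 1) * stack$frame_interval_s,
               f_tubule = fr, ok = is.finite(fr))
  })
  do.call(rbind, rows)
}
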