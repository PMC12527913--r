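#' Tubule fraction of the ER within a region
#'
#' The tubule fraction is the tubular ER area divided by the total
#' (tubule + sheet) ER area inside the region; background pixels never enter
#' the denominator.
#'
#' @param mask A [class_mask()].
#' @param roi Region restriction: `NULL` (whole image), a logical matrix of
#'   the mask's size, a closed [contour()] or a [front_roi()].
#' @param roi_id Optional region label carried into the result.
#' @return A list of class `fraction_result`: `f_tubule` in \[0, 1\],
#'   `area_tubule`, `area_sheet` (square micrometres), `roi_id`.
#' @export
tubule_fraction <- function(mask, roi = NULL, roi_id = NULL) {
  if (!inherits(mask, "class_mask")) stopf("mask must be a class_mask")
  sel <- roi_selector(roi, dim(mask$data), mask$pixel_size)
  vals <- mask$data[sel]
  px_area <- mask$pixel_size^2
  a_t <- sum(vals == 1L) * px_area
  a_s <- sum(vals == 2L) * px_area
  if (a_t + a_s == 0) stopf("empty ER in ROI")
  structure(list(f_tubule = a_t / (a_t + a_s),
                 area_tubule = a_t, area_sheet = a_s, roi_id = roi_id),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat(sprintf("<fraction_result> f_tubule = %.3f (tubule %.2f um^2, sheet %.2f um^2)\n",
              x$f_tubule, x$area_tubule, x$area_sheet))
  invisible(x)
}

roi_selector <- function(roi, dm, pixel_size) {
  if (is.null(roi)) return(matrix(TRUE, dm[1], dm[2]))
  if (is.logical(roi) || (is.matrix(roi) && all(roi %in% c(0, 1)))) {
    roi <- matrix(as.logical(roi), nrow = nrow(roi))
    if (!all(dim(roi) == dm)) stopf("ROI matrix dimensions do not match the mask")
    return(roi)
  }
  rasterize_roi(roi, dm, pixel_size)
}

#' Fraction of a marker's intensity in the cell-front region
#'
#' Background-subtracted summed intensity inside the front ROI divided by the
#' background-subtracted summed intensity of the whole cell (the classical
#' front-enrichment readout for the sheet marker Climp63). Background is the
#' median intensity of the extracellular region; negative values after
#' subtraction are truncated to zero.
#'
#' @param img An [er_image()].
#' @param front Front region: logical matrix, closed [contour()] or
#'   [front_roi()].
#' @param cell_mask Whole-cell region in the same forms.
#' @return Scalar in \[0, 1\].
#' @export
front_intensity_fraction <- function(img, front, cell_mask) {
  img <- as_er_image(img)
  cm <- roi_selector(cell_mask, dim(img$data), img$pixel_size)
  fm <- roi_selector(front, dim(img$data), img$pixel_size)
  if (!any(cm)) stopf("cell mask is empty")
  bg <- if (any(!cm)) stats::median(img$data[!cm]) else 0
  corr <- pmax(img$data - bg, 0)
  denom <- sum(corr[cm])
  if (denom <= 0) stopf("whole-cell intensity is <= 0 after background subtraction")
  sum(corr[fm & cm]) / denom
}

#' Mean distribution from the edge (MDE)
#'
#' Normalizes a component's signal within the cell to a probability density
#' and returns the density-weighted mean Euclidean distance (micrometres) to
#' the wound-edge contour. A low MDE means the component is polarized toward
#' the migrating edge.
#'
#' @param x Signal: an [er_image()] (intensity-weighted) or a [class_mask()]
#'   together with `component`.
#' @param cell_mask Cell region: logical matrix or closed [contour()].
#' @param wound_edge [contour()] of the wound edge.
#' @param component For a class-mask input: `"tubule"`, `"sheet"` or `"er"`
#'   (tubule + sheet).
#' @param cell_id Optional cell identifier carried into the result.
#' @return A list of class `mde_result` with `mde` (micrometres),
#'   `component`, `cell_id`.
#' @export
mde <- function(x, cell_mask, wound_edge, component = c("er", "tubule", "sheet"),
                cell_id = NULL) {
  component <- match.arg(component)
  if (inherits(x, "class_mask")) {
    w <- switch(component,
                tubule = x$data == 1L,
                sheet = x$data == 2L,
                er = x$data != 0L)
    w <- w * 1.0
    px <- x$pixel_size
  } else {
    x <- as_er_image(x)
    w <- x$data
    px <- x$pixel_size
    component <- "intensity"
  }
  cm <- roi_selector(cell_mask, dim(w), px)
  w[!cm] <- 0
  tot <- sum(w)
  if (tot <= 0) stopf("zero total signal within the cell mask")
  idx <- which(w > 0, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 0.5) * px, (idx[, 2] - 0.5) * px)
  d <- dist_to_contour(pts, wound_edge)
  structure(list(mde = sum(d * w[w > 0]) / tot, component = component,
                 cell_id = cell_id),
            class = "mde_result")
}

#' @export
print.mde_result <- function(x, ...) {
  cat(sprintf("<mde_result> MDE = %.3f um (%s)\n", x$mde, x$component))
  invisible(x)
}

#' Cell shape index
#'
#' Perimeter divided by the square root of the area, a standard proxy for the
#' epithelial jamming state (square: 4; circle: 2 sqrt(pi) ~ 3.545).
#'
#' @param cell Closed, simple [contour()] (self-intersecting polygons error
#'   at construction).
#' @return Dimensionless scalar.
#' @export
shape_index <- function(cell) {
  cell <- as_contour(cell)
  if (!cell$closed) stopf("shape index is defined for closed contours")
  contour_perimeter(cell) / sqrt(contour_area(cell))
}

#' Pearson correlation between estimated and reference fractions
#'
#' The standard product-moment correlation used to validate automated tubule
#' fractions against reference (manual or ground-truth) values.
#'
#' @param estimates,truths Paired numeric vectors (>= 3 values each).
#' @return A list with `r`, `n`, and the residual standard deviation `rmse`.
#' @export
validate_fractions <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stopf("series lengths differ")
  if (length(estimates) < 3L) stopf("need at least 3 paired values")
  if (stats::sd(estimates) == 0 || stats::sd(truths) == 0) {
    stopf("zero variance in a series; correlation undefined")
  }
  list(r = stats::cor(estimates, truths), n = length(estimates),
       rmse = sqrt(mean((estimates - truths)^2)))
}
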