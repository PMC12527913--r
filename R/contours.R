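#' Planar contour in micrometres
#'
#' A contour is an ordered set of planar vertices in micrometres, open
#' (a polyline such as a wound-edge arc) or closed (a simple polygon such as
#' a cell outline). Image coordinates follow the y-down convention; pixel
#' indices are converted through pixel centers: pixel (i, j) (column, row,
#' 1-based) maps to ((i - 0.5) * pixel_size, (j - 0.5) * pixel_size).
#'
#' @param x,y Numeric vertex coordinates (micrometres), or `x` may be a
#'   two-column matrix.
#' @param closed Logical; `TRUE` for polygons.
#' @param pixel_size Optional micrometres-per-pixel used when the vertices
#'   were converted from image coordinates.
#' @param id Optional identifier.
#' @param validate Check closed contours for self-intersection (default
#'   `TRUE`; traced level-set polygons skip the check).
#' @return An object of class `er_contour`.
#' @export
#' @examples
#' sq <- contour(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' contour_perimeter(sq)
contour <- function(x, y = NULL, closed = TRUE, pixel_size = NULL, id = NULL,
                    validate = TRUE) {
  v <- if (is.null(y)) as.matrix(x) else cbind(as.numeric(x), as.numeric(y))
  if (ncol(v) != 2L) stopf("contour vertices must be two-dimensional")
  storage.mode(v) <- "double"
  if (nrow(v) >= 2L) {
    dup <- rowSums(abs(diff(v))) == 0
    if (any(dup)) v <- v[c(TRUE, !dup), , drop = FALSE]
    if (closed && nrow(v) > 1L &&
        all(abs(v[1L, ] - v[nrow(v), ]) < 1e-12)) {
      v <- v[-nrow(v), , drop = FALSE]
    }
  }
  if (nrow(v) < 3L) stopf("a contour needs at least 3 distinct vertices")
  obj <- structure(
    list(vertices = v, closed = isTRUE(closed),
         pixel_size = pixel_size, id = id),
    class = "er_contour")
  if (obj$closed && validate && !is_simple_polygon(v)) {
    stopf("closed contour is self-intersecting; expected a simple polygon")
  }
  obj
}

#' @export
print.er_contour <- function(x, ...) {
  cat(sprintf("<er_contour> %s, %d vertices%s\n",
              if (x$closed) "closed" else "open", nrow(x$vertices),
              if (is.null(x$id)) "" else paste0(", id=", x$id)))
  invisible(x)
}

as_contour <- function(x, ...) {
  if (inherits(x, "er_contour")) x else contour(x, ...)
}

# segment intersection test for polygon simplicity (O(n^2); contours are small)
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges sharing a vertex with edge i
    if (!length(js)) next
    if (any(segments_intersect(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- p2 - p1
  e <- cbind(q2[, 1] - q1[, 1], q2[, 2] - q1[, 2])
  denom <- d[1] * e[, 2] - d[2] * e[, 1]
  wx <- q1[, 1] - p1[1]; wy <- q1[, 2] - p1[2]
  t <- (wx * e[, 2] - wy * e[, 1]) / denom
  u <- (wx * d[2] - wy * d[1]) / denom
  ok <- abs(denom) > 1e-14
  ok & t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12
}

#' Contour perimeter (closed) or arc length (open), in micrometres
#' @param ct An [contour()] object.
#' @return Length in micrometres.
#' @export
contour_perimeter <- function(ct) {
  v <- as_contour(ct)$vertices
  if (as_contour(ct)$closed) v <- rbind(v, v[1L, ])
  sum(sqrt(rowSums(diff(v)^2)))
}

#' Polygon area by the shoelace formula, in square micrometres
#' @param ct A closed [contour()].
#' @return Area (always positive).
#' @export
contour_area <- function(ct) {
  ct <- as_contour(ct)
  if (!ct$closed) stopf("area is defined for closed contours only")
  v <- ct$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Test whether points fall inside a closed contour
#'
#' Even-odd (crossing-number) rule; points on the boundary count as inside.
#'
#' @param pts Two-column matrix of points (micrometres).
#' @param ct A closed [contour()].
#' @return Logical vector.
#' @export
points_in_contour <- function(pts, ct) {
  ct <- as_contour(ct)
  v <- ct$vertices
  n <- nrow(v)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a contour treated as a polyline
#'
#' @param pts Two-column matrix of points.
#' @param ct A [contour()]; closed contours contribute all boundary segments.
#' @return Numeric vector of Euclidean distances (micrometres).
#' @export
dist_to_contour <- function(pts, ct) {
  ct <- as_contour(ct)
  v <- ct$vertices
  if (ct$closed) v <- rbind(v, v[1L, ])
  n <- nrow(v)
  pts <- matrix(as.numeric(pts), ncol = 2)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1L)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    dx <- v[i + 1L, 1] - ax; dy <- v[i + 1L, 2] - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - ax) * dx + (pts[, 2] - ay) * dy) / L2))
    d2 <- (pts[, 1] - (ax + t * dx))^2 + (pts[, 2] - (ay + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}
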