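#' Multi-scale pixel feature stack for ER segmentation
#'
#' Computes the classical trainable-segmentation filter bank: per scale a
#' Gaussian blur, Sobel gradient magnitude, both Hessian eigenvalues and a
#' difference of Gaussians (scale vs 2 x scale), plus membrane projections:
#' z-aggregations (sum, mean, max, min, median, std) over the responses of a
#' thin line kernel rotated through `n_orient` orientations. The image is
#' normalized by its maximum first, so downstream classification is invariant
#' to uniform intensity rescaling.
#'
#' @param img An [er_image()] (or plain matrix).
#' @param scales Numeric vector of Gaussian scales in pixels (each >= 1).
#' @param membrane_size Line-kernel length in pixels (odd; default 19).
#' @param n_orient Number of line-kernel orientations (default 30).
#' @return An object of class `feature_stack`: a list with `planes` (named
#'   list of matrices), `config` and its `hash`.
#' @export
compute_features <- function(img, scales = c(1, 2, 4, 8),
                             membrane_size = 19L, n_orient = 30L) {
  img <- as_er_image(img)
  if (!length(scales) || any(scales < 1)) stopf("scales must be >= 1 px")
  x <- img$data
  if (min(dim(x)) < membrane_size) {
    stopf("image (%d x %d) smaller than the largest kernel (%d px)",
          nrow(x), ncol(x), membrane_size)
  }
  mx <- max(x)
  if (mx > 0) x <- x / mx
  planes <- list(original = x)
  for (s in scales) {
    g <- gauss_smooth(x, s)
    planes[[sprintf("gaussian_%g", s)]] <- g
    gx <- conv2_rep(g, sobel_kx()); gy <- conv2_rep(g, t(sobel_kx()))
    planes[[sprintf("sobel_%g", s)]] <- sqrt(gx^2 + gy^2)
    lxx <- conv2_rep(g, matrix(c(1, -2, 1), 3, 1))
    lyy <- conv2_rep(g, matrix(c(1, -2, 1), 1, 3))
    lxy <- conv2_rep(g, matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1), 3, 3) / 4)
    tr <- lxx + lyy
    disc <- sqrt(pmax((lxx - lyy)^2 + 4 * lxy^2, 0))
    planes[[sprintf("hessian_e1_%g", s)]] <- (tr + disc) / 2
    planes[[sprintf("hessian_e2_%g", s)]] <- (tr - disc) / 2
    planes[[sprintf("dog_%g", s)]] <- gauss_smooth(x, 2 * s) - g
  }
  resp <- matrix(0, length(x), n_orient)
  s1 <- s2 <- numeric(length(x))
  mx <- rep(-Inf, length(x)); mn <- rep(Inf, length(x))
  for (k in seq_len(n_orient)) {
    th <- (k - 1) * pi / n_orient
    r <- as.vector(conv2_rep(x, line_kernel(membrane_size, th)))
    resp[, k] <- r
    s1 <- s1 + r; s2 <- s2 + r^2
    mx <- pmax(mx, r); mn <- pmin(mn, r)
  }
  dm <- dim(x)
  planes$membrane_sum <- matrix(s1, dm[1], dm[2])
  planes$membrane_mean <- planes$membrane_sum / n_orient
  planes$membrane_max <- matrix(mx, dm[1], dm[2])
  planes$membrane_min <- matrix(mn, dm[1], dm[2])
  # median of n_orient values per pixel via a partial rowwise sort
  mid <- if (n_orient %% 2L == 0L) c(n_orient %/% 2L, n_orient %/% 2L + 1L)
         else (n_orient + 1L) %/% 2L
  planes$membrane_median <- matrix(
    apply(resp, 1, function(v) mean(sort.int(v, partial = mid)[mid])),
    dm[1], dm[2])
  planes$membrane_std <- matrix(
    sqrt(pmax((s2 - s1^2 / n_orient) / (n_orient - 1), 0)), dm[1], dm[2])
  config <- list(scales = as.numeric(scales),
                 membrane_size = as.integer(membrane_size),
                 n_orient = as.integer(n_orient),
                 plane_names = names(planes))
  structure(list(planes = planes, config = config,
                 hash = rlang::hash(config), pixel_size = img$pixel_size),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d planes of %d x %d px (hash %s)\n",
              length(x$planes), nrow(x$planes[[1]]), ncol(x$planes[[1]]),
              substr(x$hash, 1, 8)))
  invisible(x)
}

# replicate-boundary convolution (EBImage filter2 is FFT-based); images
# smaller than the kernel are replicate-padded and cropped back
conv2_rep <- function(x, k) {
  pad_x <- max(0L, ceiling((nrow(k) + 1L - nrow(x)) / 2))
  pad_y <- max(0L, ceiling((ncol(k) + 1L - ncol(x)) / 2))
  if (pad_x == 0L && pad_y == 0L) {
    return(EBImage::filter2(x, k, boundary = "replicate"))
  }
  xi <- c(rep(1L, pad_x), seq_len(nrow(x)), rep(nrow(x), pad_x))
  yi <- c(rep(1L, pad_y), seq_len(ncol(x)), rep(ncol(x), pad_y))
  big <- EBImage::filter2(x[xi, yi], k, boundary = "replicate")
  big[pad_x + seq_len(nrow(x)), pad_y + seq_len(ncol(x))]
}

gauss_smooth <- function(x, sigma) {
  # separable Gaussian; EBImage::gblur pads internally but clips small images,
  # so use an explicit truncated kernel
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  conv2_rep(conv2_rep(x, matrix(g, ncol = 1)), matrix(g, nrow = 1))
}

sobel_kx <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8

# thin line kernel of given length through the center at angle th
line_kernel <- function(size, th) {
  r <- (size - 1) / 2
  k <- matrix(0, size, size)
  u <- c(cos(th), sin(th))
  for (i in -r:r) {
    p <- round(i * u)
    k[p[1] + r + 1, p[2] + r + 1] <- 1
  }
  k / sum(k)
}

#' Feature matrix at given pixel indices
#' @param stack A [compute_features()] result.
#' @param idx Integer vector of linear pixel indices (default all pixels).
#' @return Numeric matrix, one row per pixel, one column per plane.
#' @keywords internal
feature_matrix <- function(stack, idx = NULL) {
  n <- length(stack$planes[[1]])
  idx <- idx %||% seq_len(n)
  out <- vapply(stack$planes, function(p) p[idx], numeric(length(idx)))
  colnames(out) <- names(stack$planes)
  out
}
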