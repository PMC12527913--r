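#' Calibrated fluorescence image
#'
#' A thin wrapper around a 2D intensity matrix indexed `[x, y]` (y-down image
#' convention, matching EBImage) with the pixel size in micrometres per pixel.
#'
#' @param data Numeric matrix of non-negative, finite intensities.
#' @param pixel_size Micrometres per pixel (> 0).
#' @param channel Optional channel label (e.g. "Sec61b", "paxillin").
#' @param t_index Optional time index for frames of a stack.
#' @return An object of class `er_image`.
#' @export
er_image <- function(data, pixel_size, channel = NULL, t_index = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)) || any(data < 0)) {
    stopf("image intensities must be finite and >= 0")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(list(data = data, pixel_size = pixel_size,
                 channel = channel, t_index = t_index),
            class = "er_image")
}

#' @export
print.er_image <- function(x, ...) {
  cat(sprintf("<er_image> %d x %d px, %.4g um/px%s\n",
              nrow(x$data), ncol(x$data), x$pixel_size,
              if (is.null(x$channel)) "" else paste0(", channel=", x$channel)))
  invisible(x)
}

as_er_image <- function(x, pixel_size = NULL) {
  if (inherits(x, "er_image")) return(x)
  er_image(x, pixel_size %||% 1)
}

#' Per-pixel ER class mask
#'
#' Integer matrix with the fixed palette 0 = background, 1 = tubule,
#' 2 = sheet, carrying the producing model's feature-configuration hash as
#' provenance.
#'
#' @param data Integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size Micrometres per pixel.
#' @param model_hash Provenance string (hash of the producing model).
#' @return An object of class `class_mask`.
#' @export
class_mask <- function(data, pixel_size, model_hash = NA_character_) {
  data <- as.matrix(data)
  if (!all(data %in% 0:2)) stopf("class mask values must be in {0, 1, 2}")
  storage.mode(data) <- "integer"
  structure(list(data = data, pixel_size = pixel_size,
                 model_hash = model_hash),
            class = "class_mask")
}

#' @export
print.class_mask <- function(x, ...) {
  tab <- tabulate(x$data + 1L, nbins = 3L)
  cat(sprintf("<class_mask> %d x %d px: %d bg, %d tubule, %d sheet\n",
              nrow(x$data), ncol(x$data), tab[1], tab[2], tab[3]))
  invisible(x)
}
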