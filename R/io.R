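# File formats: contours as CSV (id, vertex_index, x_um, y_um) or
# GeoJSON-like JSON; class masks as 8-bit TIFF (palette 0 = background,
# 1 = tubule, 2 = sheet); images as 32-bit float TIFF with a JSON sidecar
# holding the calibration; tables as plain comma/UTF-8/point-decimal CSV.
# All writers are deterministic so write -> read -> write is byte-identical.

#' Write / read contours as CSV
#'
#' @param contours A [contour()] or list of contours.
#' @param path File path.
#' @param closed Are the stored contours closed polygons (applied on read)?
#' @return `write_contour_csv` returns `path` invisibly; `read_contour_csv`
#'   a named list of contours.
#' @export
write_contour_csv <- function(contours, path) {
  if (inherits(contours, "er_contour")) contours <- list(contours)
  rows <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    id <- ct$id %||% as.character(i)
    data.frame(id = id, vertex_index = seq_len(nrow(ct$vertices)),
               x_um = ct$vertices[, 1], y_um = ct$vertices[, 2])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path, closed = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stopf("contour CSV must have columns %s", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$vertex_index), ]
    contour(d$x_um, d$y_um, closed = closed, id = as.character(d$id[1]))
  })
  out[order(names(out))]
}

#' Write / read contours as GeoJSON-like JSON
#'
#' @param contours A [contour()] or list of contours.
#' @param path File path.
#' @return A named list of contours on read.
#' @export
write_contour_json <- function(contours, path) {
  if (inherits(contours, "er_contour")) contours <- list(contours)
  feats <- lapply(seq_along(contours), function(i) {
    ct <- contours[[i]]
    list(type = "Feature",
         properties = list(id = ct$id %||% as.character(i),
                           closed = ct$closed),
         geometry = list(
           type = if (ct$closed) "Polygon" else "LineString",
           coordinates = if (ct$closed) list(unname(as.matrix(ct$vertices)))
                         else unname(as.matrix(ct$vertices))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_json
#' @export
read_contour_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(j$features, function(f) {
    closed <- isTRUE(f$properties$closed)
    co <- f$geometry$coordinates
    if (closed) co <- co[[1]]
    v <- do.call(rbind, lapply(co, function(p) c(p[[1]], p[[2]])))
    contour(v, closed = closed, id = f$properties$id)
  })
  names(out) <- vapply(j$features, function(f) f$properties$id, character(1))
  out
}

#' Write / read a class mask as 8-bit TIFF
#'
#' Fixed palette: 0 = background, 1 = tubule, 2 = sheet. The pixel size is
#' stored in a JSON sidecar (`<path>.json`).
#'
#' @param mask A [class_mask()].
#' @param path TIFF path.
#' @return The mask on read.
#' @export
write_mask_tiff <- function(mask, path) {
  if (!inherits(mask, "class_mask")) stopf("mask must be a class_mask")
  tiff::writeTIFF(t(mask$data) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = mask$pixel_size,
                            palette = c(background = 0, tubule = 1, sheet = 2),
                            model_hash = mask$model_hash),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  class_mask(t(m), pixel_size = meta$pixel_size_um,
             model_hash = meta$model_hash %||% NA_character_)
}

#' Write / read a calibrated intensity image as 32-bit float TIFF
#'
#' @param img An [er_image()].
#' @param path TIFF path; pixel size and channel go to a JSON sidecar.
#' @return The image on read.
#' @export
write_image_tiff <- function(img, path) {
  img <- as_er_image(img)
  # TIFF floats are stored on [0, 1]; the intensity scale goes to the sidecar
  sc <- max(img$data, 1)
  tiff::writeTIFF(t(img$data) / sc, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(pixel_size_um = img$pixel_size,
                            channel = img$channel, intensity_scale = sc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  er_image(t(m) * (meta$intensity_scale %||% 1),
           pixel_size = meta$pixel_size_um,
           channel = if (is.null(meta$channel)) NULL else meta$channel)
}

#' Write a kymograph as TIFF plus JSON sidecar
#'
#' The sidecar records the sampling line, calibration and (optionally) the
#' flow call so a run is reproducible from its artifacts.
#'
#' @param k A [kymograph()].
#' @param path TIFF path.
#' @param flow Optional [flow_direction()] result to embed.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(k, path, flow = NULL) {
  if (!inherits(k, "kymograph")) stopf("k must be a kymograph")
  mx <- max(k$data)
  tiff::writeTIFF(t(k$data) / max(mx, 1e-300), path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(
    list(space_step_um = k$space_step_um,
         frame_interval_s = k$frame_interval_s,
         line = unname(as.matrix(k$line)), intensity_scale = mx,
         flow = flow),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a tidy metrics table as CSV
#'
#' Columns follow the tidy convention `image_id, cell_id, roi, metric,
#' value`; numeric column names elsewhere in the package carry units
#' (`_um`, `_um_inv`, `_deg`).
#'
#' @param df Data frame of metrics.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write run configuration (YAML, JSON accepted)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_config
#' @param config Named list to store.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}
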