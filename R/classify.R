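ER_CLASSES <- c("tubule", "sheet", "background")

#' Train the three-class ER pixel classifier
#'
#' Fits a random-forest (decision-tree ensemble) pixel classifier on sparse
#' labeled pixels, separating thin peripheral ER tubules, dense bright ER
#' sheets, and background. Mirrors the interactive trainable-segmentation
#' workflow: features are the multi-scale filter bank of
#' [compute_features()], labels come from manually (or synthetically) marked
#' regions.
#'
#' @param stack A [compute_features()] stack of the training image.
#' @param labels Integer matrix of the same size as the image: 0 = unlabeled,
#'   1 = tubule, 2 = sheet, 3 = background. Alternatively a data frame with
#'   columns `idx` (linear pixel index) and `class` (values 1:3 or class
#'   names).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `er_classifier` with the fitted ensemble, the
#'   feature configuration (and hash) it expects, the class levels and the
#'   out-of-bag accuracy `oob_accuracy`.
#' @export
train_classifier <- function(stack, labels, n_trees = 100L, seed = 1L) {
  if (!inherits(stack, "feature_stack")) stopf("stack must be a feature_stack")
  if (is.matrix(labels)) {
    idx <- which(labels != 0L)
    cls <- labels[idx]
  } else {
    idx <- labels$idx
    cls <- labels$class
    if (is.character(cls) || is.factor(cls)) {
      cls <- match(as.character(cls), ER_CLASSES)
    }
  }
  if (!all(cls %in% 1:3)) stopf("labels must be 1 (tubule), 2 (sheet) or 3 (background)")
  missing <- setdiff(1:3, unique(cls))
  if (length(missing)) {
    stopf("no labeled pixels for class: %s",
          paste(ER_CLASSES[missing], collapse = ", "))
  }
  fm <- feature_matrix(stack, idx)
  df <- as.data.frame(fm)
  df$.class <- factor(ER_CLASSES[cls], levels = ER_CLASSES)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, mtry = floor(sqrt(ncol(fm))),
    probability = TRUE, seed = as.integer(seed), num.threads = 1L)
  oob_pred <- max.col(fit$predictions, ties.method = "first")
  structure(list(forest = fit,
                 classes = ER_CLASSES,
                 config = stack$config,
                 feature_hash = stack$hash,
                 seed = as.integer(seed),
                 n_trees = as.integer(n_trees),
                 oob_accuracy = mean(ER_CLASSES[oob_pred] == df$.class)),
            class = "er_classifier")
}

#' @export
print.er_classifier <- function(x, ...) {
  cat(sprintf("<er_classifier> %d trees, OOB accuracy %.3f, features %s\n",
              x$n_trees, x$oob_accuracy, substr(x$feature_hash, 1, 8)))
  invisible(x)
}

#' Classify every pixel of an image into tubule / sheet / background
#'
#' Applies a trained [train_classifier()] model; per-pixel argmax of the
#' ensemble class probabilities, ties broken by the fixed class order
#' tubule < sheet < background.
#'
#' @param model An `er_classifier`.
#' @param img An [er_image()], or a precomputed [compute_features()] stack
#'   (whose configuration hash must match the model's).
#' @return A [class_mask()] (palette 0 = background, 1 = tubule, 2 = sheet)
#'   carrying the model hash as provenance.
#' @export
classify <- function(model, img) {
  if (!inherits(model, "er_classifier")) stopf("model must be an er_classifier")
  if (inherits(img, "feature_stack")) {
    stack <- img
  } else {
    img <- as_er_image(img)
    stack <- do.call(compute_features, c(list(img), model$config[
      c("scales", "membrane_size", "n_orient")]))
  }
  if (!identical(stack$hash, model$feature_hash)) {
    stopf("feature configuration hash mismatch: model %s vs stack %s",
          model$feature_hash, stack$hash)
  }
  fm <- feature_matrix(stack)
  pred <- stats::predict(model$forest, data = as.data.frame(fm),
                         num.threads = 1L)$predictions
  pred <- pred[, ER_CLASSES, drop = FALSE]
  cls <- max.col(pred, ties.method = "first")  # tubule < sheet < background
  pal <- c(1L, 2L, 0L)  # mask palette: background 0, tubule 1, sheet 2
  mk <- matrix(pal[cls], nrow = nrow(stack$planes[[1]]))
  class_mask(mk, pixel_size = stack$pixel_size,
             model_hash = rlang::hash(model$forest$forest))
}

#' Save / load a trained ER classifier
#'
#' Serialization round-trips the model bit-identically (the loaded model
#' reproduces predictions exactly).
#'
#' @param model An `er_classifier`.
#' @param path Destination file (RDS bundle).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  if (!inherits(model, "er_classifier")) stopf("model must be an er_classifier")
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "er_classifier")) stopf("%s is not an er_classifier bundle", path)
  model
}
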