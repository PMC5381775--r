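#' Confusion summary of a classifier on a labeled pixel set
#'
#' Tabulates model predictions against the true labels of a training (or
#' held-out) set. Rows of the count table are true classes, columns are
#' predicted classes; accuracy is `1 - error_pixels / total_pixels`, the
#' convention behind the headline per-pixel accuracy of pixel classifiers.
#'
#' @param model A `stain_classifier`.
#' @param training_set A `training_set` tibble sharing the same class
#'   codes.
#' @return A `stain_confusion` object: 3 x 3 `counts` matrix,
#'   `total_pixels`, `error_pixels`, `accuracy`.
#' @export
evaluate_training_accuracy <- function(model, training_set) {
  training_set <- as_training_set(training_set)
  pred <- predict(model, training_set)
  counts <- table(true = training_set$class, predicted = pred)
  counts <- unclass(counts)[STAIN_LEVELS, STAIN_LEVELS]
  total <- sum(counts)
  errors <- total - sum(diag(counts))
  structure(
    list(
      counts = counts,
      total_pixels = total,
      error_pixels = errors,
      accuracy = 1 - errors / total
    ),
    class = "stain_confusion"
  )
}

#' @export
print.stain_confusion <- function(x, ...) {
  cat("<stain_confusion> accuracy ", sprintf("%.4f", x$accuracy),
      " (", x$error_pixels, " / ", x$total_pixels, " misclassified)\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname evaluate_training_accuracy
#' @param x A `stain_confusion`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`true_class`, `predicted_class`,
#'   `count`); `glance()`: one row with totals and accuracy.
#' @method tidy stain_confusion
#' @export
tidy.stain_confusion <- function(x, ...) {
  tibble::tibble(
    true_class = stain_factor(rep(rownames(x$counts), times = 3)),
    predicted_class = stain_factor(rep(colnames(x$counts), each = 3)),
    count = as.integer(x$counts)
  )
}

#' @rdname evaluate_training_accuracy
#' @method glance stain_confusion
#' @export
glance.stain_confusion <- function(x, ...) {
  tibble::tibble(
    total_pixels = x$total_pixels,
    error_pixels = x$error_pixels,
    accuracy = x$accuracy
  )
}

#' Write a confusion report as CSV
#'
#' One row per (true class, predicted class) pair plus a trailing summary
#' row holding totals and accuracy.
#'
#' @param confusion A `stain_confusion`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(confusion, path) {
  long <- tidy(confusion) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.factor), as.character))
  summary_row <- tibble::tibble(
    true_class = "TOTAL",
    predicted_class = sprintf("accuracy=%.6f", confusion$accuracy),
    count = confusion$total_pixels
  )
  readr::write_csv(dplyr::bind_rows(long, summary_row), path)
  invisible(path)
}

#' Render a label map as a color overlay image
#'
#' @param label_map A `label_map`.
#' @param palette A 3 x 3 matrix of 0--255 RGB rows, one per class in code
#'   order (default [stain_palette()]: red, blue, white).
#' @return An `rgb_image` of the same dimensions with each pixel painted
#'   its class color.
#' @export
render_overlay <- function(label_map, palette = stain_palette()) {
  stopifnot(is.matrix(label_map))
  palette <- as.matrix(palette)
  if (nrow(palette) != 3 || ncol(palette) != 3 || any(is.na(palette))) {
    stop("palette must assign one RGB triple to each of the three classes",
         call. = FALSE)
  }
  h <- nrow(label_map); w <- ncol(label_map)
  idx <- as.integer(label_map)
  as_rgb_image(array(c(palette[idx, 1], palette[idx, 2], palette[idx, 3]),
                     dim = c(h, w, 3)))
}
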