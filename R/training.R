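#' Assemble a training set from labeled reference crops
#'
#' Each reference crop is a small micrograph dominated by one stain class
#' (in practice around 100 x 100 px). Every pixel of every crop contributes
#' one (R, G, B) feature row carrying the crop's class label; rows keep
#' crop-list order then row-major pixel order so that training is
#' reproducible on order-sensitive trainers.
#'
#' @param crops A data frame with columns `path` (PNG/TIFF file) and `class`
#'   (stain class name or code), or columns `image` (list of `rgb_image`)
#'   and `class` for in-memory crops, e.g. from [simulate_training_crops()].
#' @return A `training_set` tibble with columns `r`, `g`, `b` (integer
#'   0--255), `class` (factor) and `crop` (source identifier), plus
#'   per-class counts in `attr(, "per_class_counts")`.
#' @seealso [train_stain_classifier()]
#' @export
load_training_crops <- function(crops) {
  crops <- tibble::as_tibble(crops)
  if (!"class" %in% names(crops)) {
    stop("`crops` needs a `class` column", call. = FALSE)
  }
  crops$class <- stain_factor(crops$class)
  missing_cls <- setdiff(STAIN_LEVELS, as.character(unique(crops$class)))
  if (length(missing_cls) > 0) {
    stop("no reference crop supplied for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  if ("image" %in% names(crops)) {
    images <- crops$image
    ids <- if ("crop" %in% names(crops)) {
      crops$crop
    } else {
      paste0("crop_", seq_len(nrow(crops)))
    }
  } else if ("path" %in% names(crops)) {
    images <- purrr::map(crops$path, read_rgb_image)
    ids <- as.character(crops$path)
  } else {
    stop("`crops` needs a `path` or `image` column", call. = FALSE)
  }
  rows <- purrr::pmap(
    list(images, crops$class, ids),
    function(img, cls, id) {
      as_pixel_tbl(img) |>
        dplyr::transmute(.data$r, .data$g, .data$b,
                         class = cls, crop = id)
    }
  )
  as_training_set(dplyr::bind_rows(rows))
}

#' Construct / validate a `training_set` tibble
#'
#' @param x A data frame with columns `r`, `g`, `b` and `class` (optionally
#'   `crop`).
#' @return A validated `training_set` tibble with a `per_class_counts`
#'   attribute.
#' @export
as_training_set <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("r", "g", "b", "class") %in% names(x)))
  if (!"crop" %in% names(x)) x$crop <- NA_character_
  x$class <- stain_factor(x$class)
  chans <- as.matrix(x[, c("r", "g", "b")])
  if (any(chans < 0 | chans > 255)) {
    stop("feature channels must lie in [0, 255]", call. = FALSE)
  }
  counts <- table(x$class)
  attr(x, "per_class_counts") <- stats::setNames(as.integer(counts),
                                                 names(counts))
  class(x) <- c("training_set", class(x))
  x
}

#' @export
print.training_set <- function(x, ...) {
  counts <- attr(x, "per_class_counts")
  cat("<training_set> ", nrow(x), " pixels (",
      paste(names(counts), counts, sep = ": ", collapse = ", "), ")\n",
      sep = "")
  NextMethod()
}
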