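#' Read an 8-bit RGB micrograph
#'
#' Reads a PNG or TIFF file into an integer H x W x 3 array with channel
#' values in 0--255. Grayscale images are replicated across channels, an
#' alpha channel is dropped, and bit depths other than 8 are rescaled to
#' 8-bit; each of these adjustments emits a warning because the pipeline is
#' defined on plain 8-bit RGB.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer array `c(height, width, 3)` of class `rgb_image`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for file: ", path,
         call. = FALSE)
  )
  if (!is.numeric(arr)) {
    stop("could not decode ", path, " as a raster image", call. = FALSE)
  }
  if (length(dim(arr)) == 2) {
    warning("grayscale image flattened to RGB on load: ", path)
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  }
  if (dim(arr)[3] == 4) {
    warning("alpha channel dropped on load: ", path)
    arr <- arr[, , 1:3, drop = FALSE]
  }
  if (dim(arr)[3] != 3) {
    stop("image is not RGB (", dim(arr)[3], " channels): ", path,
         call. = FALSE)
  }
  # readPNG/readTIFF return [0,1]; map back to the 8-bit integer grid
  as_rgb_image(round(arr * 255))
}

#' Construct / validate an `rgb_image`
#'
#' @param x Numeric H x W x 3 array with values in 0--255.
#' @return The validated integer array with class `rgb_image`.
#' @export
as_rgb_image <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 3,
            dim(x)[1] >= 1, dim(x)[2] >= 1)
  if (any(x < 0 | x > 255)) {
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  class(x) <- c("rgb_image", class(x))
  x
}

#' Write an 8-bit RGB image as PNG
#'
#' @param image An `rgb_image` (integer H x W x 3, 0--255).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Read / write a label map as grayscale PNG
#'
#' Label maps are stored as 8-bit grayscale PNGs whose pixel value is the
#' integer class code (1 = adipogenic, 2 = osteogenic, 3 = negative). The
#' round-trip is exact.
#'
#' @param path PNG path.
#' @return `read_label_map()`: an integer matrix of class `label_map`.
#' @export
read_label_map <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  as_label_map(round(m * 255))
}

#' @rdname read_label_map
#' @param label_map An integer matrix with values in 1--3.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(is.matrix(label_map))
  png::writePNG(unclass(label_map) / 255, target = path)
  invisible(path)
}

#' Construct / validate a `label_map`
#'
#' @param x Integer matrix with every entry a valid class code (1, 2 or 3).
#' @return The matrix with class `label_map`.
#' @export
as_label_map <- function(x) {
  stopifnot(is.matrix(x))
  if (!all(x %in% 1:3)) {
    stop("label map entries must be class codes 1, 2 or 3 (no unlabeled pixels)",
         call. = FALSE)
  }
  storage.mode(x) <- "integer"
  class(x) <- c("label_map", class(x))
  x
}

#' Flatten an RGB image to a pixel table
#'
#' @param image An `rgb_image`.
#' @return A tibble with one row per pixel in row-major (reading) order:
#'   `row`, `col`, and channel values `r`, `g`, `b`.
#' @export
as_pixel_tbl <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  tibble::tibble(
    row = rep(seq_len(h), times = w),
    col = rep(seq_len(w), each = h),
    r = as.integer(image[, , 1]),
    g = as.integer(image[, , 2]),
    b = as.integer(image[, , 3])
  ) |>
    dplyr::arrange(.data$row, .data$col)
}
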