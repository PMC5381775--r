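#' Confinement geometry
#'
#' Ties image coordinates to physical micrometres for a circular
#' micro-confinement. Coordinates follow the pixel-center convention:
#' pixel (row i, col j) has its center at x = j, y = i in pixel units.
#'
#' @param center_x,center_y Circle center in pixel units (continuous).
#' @param radius_px Circle radius in pixels (> 0).
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @return A `confinement_geometry` list with the fields above plus
#'   `radius_um` and `diameter_um`.
#' @export
confinement_geometry <- function(center_x, center_y, radius_px,
                                 pixel_size_um) {
  stopifnot(radius_px > 0, pixel_size_um > 0)
  structure(
    list(
      center_x = center_x, center_y = center_y,
      radius_px = radius_px, pixel_size_um = pixel_size_um,
      radius_um = radius_px * pixel_size_um,
      diameter_um = 2 * radius_px * pixel_size_um
    ),
    class = "confinement_geometry"
  )
}

#' @export
print.confinement_geometry <- function(x, ...) {
  cat(sprintf(
    "<confinement_geometry> center (%.2f, %.2f) px, radius %.2f px (%.1f um diameter at %.3f um/px)\n",
    x$center_x, x$center_y, x$radius_px, x$diameter_um, x$pixel_size_um))
  invisible(x)
}

#' Auto-detect confinement center and radius
#'
#' Estimates the circle from the cell-covered (foreground) area: for a
#' label map, foreground is every non-negative-class pixel; for an RGB
#' image, pixels whose color departs from the background model. The center
#' is the foreground centroid. The radius comes from the expected diameter
#' when supplied, otherwise from the circle of equivalent foreground area;
#' when both are available and disagree by more than 20 %, a warning is
#' emitted and the expected value wins.
#'
#' @param x A `label_map` or `rgb_image`.
#' @param pixel_size_um Micrometres per pixel.
#' @param expected_diameter_um Optional known confinement diameter in
#'   micrometres.
#' @param background_color RGB triple of the background (only used for raw
#'   images; default white 255,255,255).
#' @param background_tol Channel distance below which a raw-image pixel
#'   counts as background (default 40).
#' @return A [confinement_geometry()].
#' @export
detect_confinement <- function(x, pixel_size_um, expected_diameter_um = NULL,
                               background_color = c(255, 255, 255),
                               background_tol = 40) {
  if (inherits(x, "label_map")) {
    fg <- unclass(x) != 3L
  } else if (inherits(x, "rgb_image") ||
             (is.array(x) && length(dim(x)) == 3)) {
    d2 <- (x[, , 1] - background_color[1])^2 +
          (x[, , 2] - background_color[2])^2 +
          (x[, , 3] - background_color[3])^2
    fg <- d2 > background_tol^2
  } else if (is.matrix(x) && is.logical(x)) {
    fg <- x
  } else {
    stop("cannot detect a confinement in object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  if (!any(fg)) {
    stop("empty foreground: no cell-covered pixels found", call. = FALSE)
  }
  idx <- which(fg, arr.ind = TRUE)
  center_y <- mean(idx[, 1])
  center_x <- mean(idx[, 2])
  area_radius <- sqrt(sum(fg) / pi)
  if (is.null(expected_diameter_um)) {
    radius_px <- area_radius
  } else {
    radius_px <- expected_diameter_um / 2 / pixel_size_um
    if (abs(area_radius - radius_px) / radius_px > 0.2) {
      warning(sprintf(
        "detected foreground radius (%.1f px) deviates > 20%% from expected (%.1f px); using the expected value",
        area_radius, radius_px))
    }
  }
  confinement_geometry(center_x, center_y, radius_px, pixel_size_um)
}
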