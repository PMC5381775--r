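#' Plot an aggregate radial profile
#'
#' Draws the three class-fraction curves (mean +/- SD error bars) against
#' radial position, the standard presentation for ring-wise quantification
#' of patterned differentiation: adipogenic in red, osteogenic in blue,
#' undifferentiated in grey.
#'
#' @param object A `ring_aggregate`.
#' @param coordinate `"center"` (distance from confinement center, default)
#'   or `"wall"` (distance from the confining wall).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ring_aggregate
#' @export
autoplot.ring_aggregate <- function(object, coordinate = c("center", "wall"),
                                    ...) {
  coordinate <- match.arg(coordinate)
  xvar <- if (coordinate == "center") "r_mid_um" else "dist_wall_um"
  xlab <- if (coordinate == "center") {
    "Distance from center (µm)"
  } else {
    "Distance from wall (µm)"
  }
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(mean|sd)_"),
      names_to = c(".value", "class"), names_pattern = "(mean|sd)_(.*)"
    ) |>
    dplyr::mutate(class = stain_factor(.data$class))

  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                                     color = .data$class)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 1)),
      width = attr(object, "ring_thickness_um") / 4, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_color_manual(
      values = c(adipogenic = "#c0392b", osteogenic = "#2980b9",
                 negative = "grey40"),
      name = "Class") +
    ggplot2::labs(x = xlab, y = "Area fraction") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
}

#' @rdname autoplot.ring_aggregate
#' @param aggregate A `ring_aggregate`.
#' @export
plot_radial_profile <- function(aggregate, coordinate = c("center", "wall")) {
  autoplot.ring_aggregate(aggregate, coordinate = coordinate)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
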