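#' Segment a confinement into coaxial rings
#'
#' Builds a per-pixel ring index for concentric annuli of fixed radial
#' thickness (default 25 um). Pixel p belongs to ring k (0-based) iff
#' `k * dr <= dist(p, center) * pixel_size_um < (k + 1) * dr`, distances
#' measured from pixel centers; pixels beyond the confinement radius get
#' the OUTSIDE sentinel `NA`. The outermost ring is truncated at the
#' confinement radius, so `ring_count = ceiling(radius_um / dr)` and the
#' in-circle pixels partition exactly into the rings.
#'
#' @param geometry A [confinement_geometry()].
#' @param image_shape Integer `c(height, width)` of the image being
#'   profiled.
#' @param ring_thickness_um Ring thickness in micrometres (> 0);
#'   default 25.
#' @return A `ring_index_map`: integer matrix of 0-based ring indices (NA
#'   outside the circle) with attributes `ring_count`, `ring_thickness_um`
#'   and a `rings` tibble (`ring`, `r_inner_um`, `r_outer_um`, `r_mid_um`).
#' @export
build_ring_index <- function(geometry, image_shape, ring_thickness_um = 25) {
  if (!is.numeric(ring_thickness_um) || ring_thickness_um <= 0) {
    stop("ring thickness must be a positive length in micrometres",
         call. = FALSE)
  }
  h <- image_shape[1]; w <- image_shape[2]
  radius_um <- geometry$radius_um
  ring_count <- as.integer(ceiling(radius_um / ring_thickness_um))

  dx <- (rep(seq_len(w), each = h) - geometry$center_x)
  dy <- (rep(seq_len(h), times = w) - geometry$center_y)
  dist_um <- sqrt(dx^2 + dy^2) * geometry$pixel_size_um
  idx <- ifelse(dist_um <= radius_um,
                pmin(floor(dist_um / ring_thickness_um), ring_count - 1L),
                NA_integer_)
  m <- matrix(as.integer(idx), nrow = h, ncol = w)

  rings <- tibble::tibble(
    ring = seq_len(ring_count) - 1L,
    r_inner_um = (seq_len(ring_count) - 1L) * ring_thickness_um,
    r_outer_um = pmin(seq_len(ring_count) * ring_thickness_um, radius_um)
  ) |>
    dplyr::mutate(r_mid_um = (.data$r_inner_um + .data$r_outer_um) / 2)

  structure(m,
            ring_count = ring_count,
            ring_thickness_um = ring_thickness_um,
            radius_um = radius_um,
            rings = rings,
            class = c("ring_index_map", "matrix", "array"))
}

#' Per-ring class-area fractions of one label map
#'
#' For each ring, the fraction of pixels carrying each class:
#' `fraction_c = (pixels of class c in ring) / (pixels in ring)`. Pixels
#' outside the confinement are excluded entirely. Empty rings are kept in
#' the table with `NA` fractions (flagged, never silently 0/0).
#'
#' @param label_map A `label_map`.
#' @param ring_map A `ring_index_map` of the same dimensions.
#' @return A `ring_profile` tibble: `ring`, `r_inner_um`, `r_outer_um`,
#'   `r_mid_um`, `dist_wall_um` (confinement radius minus mid-radius),
#'   `n_pixels`, and `frac_adipogenic` / `frac_osteogenic` /
#'   `frac_negative`. Ring thickness and confinement radius ride along as
#'   attributes for aggregation-compatibility checks.
#' @export
compute_ring_fractions <- function(label_map, ring_map) {
  if (!all(dim(label_map) == dim(ring_map))) {
    stop("label map and ring index map dimensions differ", call. = FALSE)
  }
  rings <- attr(ring_map, "rings")
  ring_count <- attr(ring_map, "ring_count")
  inside <- !is.na(ring_map)
  tab <- table(
    ring = factor(ring_map[inside], levels = 0:(ring_count - 1L)),
    class = factor(unclass(label_map)[inside], levels = 1:3)
  )
  counts <- matrix(as.integer(tab), nrow = ring_count)
  n_pixels <- rowSums(counts)
  frac <- counts / ifelse(n_pixels > 0, n_pixels, NA_real_)

  profile <- rings |>
    dplyr::mutate(
      dist_wall_um = attr(ring_map, "radius_um") - .data$r_mid_um,
      n_pixels = as.integer(n_pixels),
      frac_adipogenic = frac[, 1],
      frac_osteogenic = frac[, 2],
      frac_negative = frac[, 3]
    )
  structure(profile,
            ring_thickness_um = attr(ring_map, "ring_thickness_um"),
            radius_um = attr(ring_map, "radius_um"),
            class = c("ring_profile", class(profile)))
}

profile_attr <- function(p, what) {
  a <- attr(p, what)
  if (is.null(a)) stop("profile lacks attribute '", what, "'", call. = FALSE)
  a
}

#' Aggregate replicate ring profiles into mean +/- SD curves
#'
#' Combines per-image radial profiles from replicate confinements of the
#' same diameter into per-ring arithmetic means and sample standard
#' deviations (N - 1 denominator) of each class fraction. Rings that are
#' empty in a given replicate are excluded from that ring's aggregation
#' rather than imputed as zero; SD is reported as `NA` where fewer than
#' two replicates contribute.
#'
#' @param profiles A list of `ring_profile` tibbles sharing ring thickness
#'   and confinement radius.
#' @return A `ring_aggregate` tibble: per ring, radii and both distance
#'   conventions, `n_images`, and `mean_` / `sd_` columns per class.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  thick <- vapply(profiles, profile_attr, numeric(1), "ring_thickness_um")
  radius <- vapply(profiles, profile_attr, numeric(1), "radius_um")
  if (length(unique(thick)) != 1 || length(unique(radius)) != 1) {
    stop("profiles mix ring thicknesses or confinement radii; ",
         "aggregate only replicates of one geometry", call. = FALSE)
  }
  long <- purrr::imap(profiles, ~ dplyr::mutate(tibble::as_tibble(.x),
                                                .replicate = .y)) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$n_pixels > 0)

  agg <- long |>
    dplyr::group_by(.data$ring, .data$r_inner_um, .data$r_outer_um,
                    .data$r_mid_um, .data$dist_wall_um) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      dplyr::across(
        dplyr::starts_with("frac_"),
        list(mean = mean,
             sd = ~ if (dplyr::n() >= 2) stats::sd(.x) else NA_real_),
        .names = "{.fn}_{sub('frac_', '', .col)}"
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ring)
  structure(agg,
            ring_thickness_um = thick[1],
            radius_um = radius[1],
            n_profiles = length(profiles),
            class = c("ring_aggregate", class(agg)))
}

#' Write / read an aggregate radial profile as CSV
#'
#' One row per ring with both coordinate conventions (`r_mid_um`, distance
#' from center; `dist_wall_um`, distance from the confining wall), the
#' replicate count and mean / SD per class. Reading the file back restores
#' the `ring_aggregate` exactly.
#'
#' @param aggregate A `ring_aggregate`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_profile_table()` returns the restored
#'   `ring_aggregate`.
#' @export
export_profile_table <- function(aggregate, path) {
  out <- tibble::as_tibble(aggregate) |>
    dplyr::mutate(ring_thickness_um = attr(aggregate, "ring_thickness_um"),
                  radius_um = attr(aggregate, "radius_um"))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname export_profile_table
#' @export
read_profile_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  thick <- tab$ring_thickness_um[1]
  radius <- tab$radius_um[1]
  tab <- dplyr::select(tab, -"ring_thickness_um", -"radius_um") |>
    dplyr::mutate(ring = as.integer(.data$ring),
                  n_images = as.integer(.data$n_images))
  structure(tab,
            ring_thickness_um = thick,
            radius_um = radius,
            class = c("ring_aggregate", class(tab)))
}
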