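#' Class color model for the synthetic stained colony
#'
#' Gaussian RGB color clusters per class, arranged along the gray diagonal
#' of color space the way chromogen-stained micrographs cluster: the
#' adipogenic (Oil Red O) cluster is displaced toward red, the osteogenic
#' (Fast Blue) cluster toward blue, and the stain-negative cluster sits
#' near white. Sampled colors are clipped to [0, 255] and quantized to
#' integers. The background (outside-confinement) area has its own model.
#'
#' @param means 3 x 3 numeric matrix of class mean RGB rows, in class-code
#'   order (adipogenic, osteogenic, negative).
#' @param sds Per-class isotropic channel SD (length 3 or scalar).
#' @param background_mean RGB triple for outside-confinement pixels.
#' @param background_sd Channel SD of the background.
#' @return A `stain_color_model` list.
#' @export
stain_color_model <- function(means = rbind(adipogenic = c(180, 60, 60),
                                            osteogenic = c(60, 60, 180),
                                            negative = c(225, 225, 225)),
                              sds = c(10, 10, 10),
                              background_mean = c(235, 235, 235),
                              background_sd = 3) {
  means <- as.matrix(means)
  stopifnot(nrow(means) == 3, ncol(means) == 3)
  sds <- rep_len(sds, 3)
  stopifnot(all(sds >= 0), background_sd >= 0)
  structure(list(means = unname(means), sds = sds,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "stain_color_model")
}

#' Radial differentiation layout of a simulated colony
#'
#' Encodes the center-adipogenic / periphery-osteogenic / wall-adjacent
#' undifferentiated pattern of confined stem-cell colonies. In the
#' `three_zone_step` layout, a pixel at radius r (um) is adipogenic for
#' r < `r_adipo_um`, osteogenic for `r_adipo_um` <= r < `r_osteo_um`, and
#' the rim class (default negative) beyond; `zone_probs` can soften each
#' zone into a class-probability mixture. The `logistic_blend` layout
#' replaces the two hard steps with logistic transitions of width
#' `blend_um`.
#'
#' @param r_adipo_um Outer radius of the adipogenic core (um).
#' @param r_osteo_um Outer radius of the osteogenic annulus (um); the rim
#'   extends from here to the confinement wall.
#' @param kind `"three_zone_step"` or `"logistic_blend"`.
#' @param rim_class Class of the rim zone (default `"negative"`,
#'   reflecting undifferentiated cells near the confining wall).
#' @param zone_probs Optional 3 x 3 matrix of per-zone class probabilities
#'   (rows = core/annulus/rim, columns = classes in code order); rows must
#'   sum to 1. Default: each zone is pure.
#' @param blend_um Logistic transition scale for `"logistic_blend"`.
#' @return A `radial_layout` list.
#' @export
radial_layout <- function(r_adipo_um, r_osteo_um,
                          kind = c("three_zone_step", "logistic_blend"),
                          rim_class = "negative",
                          zone_probs = NULL, blend_um = 10) {
  kind <- match.arg(kind)
  if (!(r_adipo_um > 0 && r_adipo_um <= r_osteo_um)) {
    stop("zone radii must satisfy 0 < r_adipo_um <= r_osteo_um",
         call. = FALSE)
  }
  rim_code <- match(as.character(stain_factor(rim_class)), STAIN_LEVELS)
  if (is.null(zone_probs)) {
    zone_probs <- matrix(0, 3, 3)
    zone_probs[1, 1] <- 1
    zone_probs[2, 2] <- 1
    zone_probs[3, rim_code] <- 1
  }
  zone_probs <- as.matrix(zone_probs)
  stopifnot(nrow(zone_probs) == 3, ncol(zone_probs) == 3,
            all(zone_probs >= 0),
            all(abs(rowSums(zone_probs) - 1) < 1e-9))
  structure(list(kind = kind, r_adipo_um = r_adipo_um,
                 r_osteo_um = r_osteo_um, rim_class = rim_code,
                 zone_probs = unname(zone_probs), blend_um = blend_um),
            class = "radial_layout")
}

# class-probability matrix (n x 3) at the given radii (um)
layout_probs <- function(layout, radius_um, confinement_radius_um) {
  n <- length(radius_um)
  if (layout$kind == "three_zone_step") {
    zone <- ifelse(radius_um < layout$r_adipo_um, 1L,
                   ifelse(radius_um < layout$r_osteo_um, 2L, 3L))
    layout$zone_probs[zone, , drop = FALSE]
  } else {
    # smooth occupancy of the three zones via two logistic gates
    g1 <- stats::plogis((radius_um - layout$r_adipo_um) / layout$blend_um)
    g2 <- stats::plogis((radius_um - layout$r_osteo_um) / layout$blend_um)
    occ <- cbind(1 - g1, g1 - g1 * g2, g1 * g2)
    occ <- occ / rowSums(occ)
    occ %*% layout$zone_probs
  }
}

sample_class_colors <- function(codes, color_model) {
  n <- length(codes)
  means <- color_model$means[codes, , drop = FALSE]
  sds <- color_model$sds[codes]
  cols <- means + matrix(stats::rnorm(3 * n), n, 3) * sds
  matrix(as.integer(pmin(pmax(round(cols), 0), 255)), n, 3)
}

#' Simulate a stained-colony micrograph with ground truth
#'
#' Generates a seeded synthetic RGB image of one circular confinement: for
#' each in-circle pixel a class is drawn from the radial layout at that
#' pixel's radius, then a color from that class's Gaussian color model;
#' outside pixels get the background color and the negative label. The
#' returned label map is the exact ground truth, making the simulation the
#' evaluation oracle for classifier and profiler. Randomness uses R's
#' Mersenne-Twister generator under the supplied seed, so output is
#' bitwise reproducible.
#'
#' @param diameter_um Confinement diameter in micrometres (the study
#'   geometries are 200, 400 and 800).
#' @param pixel_size_um Micrometres per pixel (default 1).
#' @param image_size Optional `c(height, width)` in px; default a square
#'   with a 10 px margin around the confinement.
#' @param color_model A [stain_color_model()].
#' @param layout A [radial_layout()]; default: adipogenic core to 25 % of
#'   the diameter, osteogenic annulus to 85 % of the radius, negative rim.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `stain_colony`: `image` (`rgb_image`), `labels`
#'   (ground-truth `label_map`), `geometry`
#'   ([confinement_geometry()]), and `params`.
#' @examples
#' col <- simulate_colony(diameter_um = 200, seed = 1)
#' table(col$labels)
#' @export
simulate_colony <- function(diameter_um = 200, pixel_size_um = 1,
                            image_size = NULL,
                            color_model = stain_color_model(),
                            layout = radial_layout(
                              r_adipo_um = diameter_um / 4,
                              r_osteo_um = 0.85 * diameter_um / 2),
                            seed) {
  stopifnot(!missing(seed))
  radius_um <- diameter_um / 2
  radius_px <- radius_um / pixel_size_um
  if (is.null(image_size)) {
    side <- ceiling(2 * radius_px) + 20L
    image_size <- c(side, side)
  }
  h <- image_size[1]; w <- image_size[2]
  geometry <- confinement_geometry((w + 1) / 2, (h + 1) / 2, radius_px,
                                   pixel_size_um)
  if (layout$r_osteo_um > radius_um + 1e-9) {
    stop("layout zone radii exceed the confinement radius", call. = FALSE)
  }

  dx <- rep(seq_len(w), each = h) - geometry$center_x
  dy <- rep(seq_len(h), times = w) - geometry$center_y
  r_um <- sqrt(dx^2 + dy^2) * pixel_size_um
  inside <- r_um <= radius_um

  withr::with_seed(seed, {
    codes <- rep(3L, h * w)
    probs <- layout_probs(layout, r_um[inside], radius_um)
    u <- stats::runif(sum(inside))
    cum1 <- probs[, 1]; cum2 <- probs[, 1] + probs[, 2]
    codes[inside] <- ifelse(u < cum1, 1L, ifelse(u < cum2, 2L, 3L))

    flat <- matrix(0L, h * w, 3)
    flat[inside, ] <- sample_class_colors(codes[inside], color_model)
    n_out <- sum(!inside)
    bg <- matrix(rep(color_model$background_mean, each = n_out), n_out, 3) +
      matrix(stats::rnorm(3 * n_out), n_out, 3) * color_model$background_sd
    flat[!inside, ] <- as.integer(pmin(pmax(round(bg), 0), 255))
  }, .rng_kind = "Mersenne-Twister")

  image <- as_rgb_image(array(flat, dim = c(h, w, 3)))
  labels <- as_label_map(matrix(codes, h, w))
  structure(
    list(image = image, labels = labels, geometry = geometry,
         params = list(diameter_um = diameter_um,
                       pixel_size_um = pixel_size_um,
                       image_size = c(h, w), seed = seed,
                       rng = "Mersenne-Twister",
                       color_model = color_model, layout = layout)),
    class = "stain_colony"
  )
}

#' Simulate pure-class training crops
#'
#' Produces small single-class reference images whose pixels are drawn
#' from the class color model, mimicking the labeled reference
#' micrographs used to train the pixel classifier. An optional
#' multiplicative shading field darkens part of each crop, emulating the
#' dark areas such reference images deliberately contain.
#'
#' @param color_model A [stain_color_model()].
#' @param crop_size Crop size in px: a side length, or `c(height, width)`
#'   (default 100).
#' @param n_per_class Crops per class (default 1).
#' @param shading Fraction in [0, 1): multiplicative attenuation applied
#'   to the left half of each crop (0 = off, default).
#' @param seed Integer seed.
#' @return A tibble with columns `crop`, `class` and `image`
#'   (list-column of `rgb_image`), ready for [load_training_crops()].
#' @export
simulate_training_crops <- function(color_model = stain_color_model(),
                                    crop_size = 100, n_per_class = 1,
                                    shading = 0, seed) {
  stopifnot(!missing(seed), all(crop_size >= 1), shading >= 0, shading < 1)
  dims <- rep_len(as.integer(crop_size), 2)
  grid <- tidyr::expand_grid(class = stain_factor(STAIN_LEVELS),
                             rep = seq_len(n_per_class))
  withr::with_seed(seed, {
    images <- purrr::map(seq_len(nrow(grid)), function(i) {
      code <- match(as.character(grid$class[i]), STAIN_LEVELS)
      cols <- sample_class_colors(rep(code, prod(dims)), color_model)
      img <- array(cols, dim = c(dims, 3))
      if (shading > 0) {
        dark_cols <- seq_len(floor(dims[2] / 2))
        img[, dark_cols, ] <- as.integer(round(img[, dark_cols, ] *
                                                 (1 - shading)))
      }
      as_rgb_image(img)
    })
  }, .rng_kind = "Mersenne-Twister")
  grid |>
    dplyr::transmute(crop = sprintf("sim_%s_%d", .data$class, .data$rep),
                     class = .data$class, image = images)
}
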