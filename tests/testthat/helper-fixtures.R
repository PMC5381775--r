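# Shared fixtures: all synthetic, generated in code at test time.

# Perfectly separable constant-color training set (one pure color per class).
constant_training_set <- function(n_per_class = 100) {
  as_training_set(data.frame(
    r = rep(c(255, 0, 255), each = n_per_class),
    g = rep(c(0, 0, 255), each = n_per_class),
    b = rep(c(0, 255, 255), each = n_per_class),
    class = rep(STAIN_LEVELS, each = n_per_class)
  ))
}

# Seeded isotropic Gaussian clusters in RGB space, one per class.
gaussian_training_set <- function(n_per_class = 1000, sd = 10, seed = 42,
                                  means = rbind(c(180, 60, 60),
                                                c(60, 60, 180),
                                                c(200, 200, 200))) {
  withr::with_seed(seed, {
    feats <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rep(means[k, ], each = n_per_class), n_per_class, 3) +
        matrix(stats::rnorm(3 * n_per_class, sd = sd), n_per_class, 3)
    }))
  })
  feats <- pmin(pmax(round(feats), 0), 255)
  as_training_set(data.frame(
    r = feats[, 1], g = feats[, 2], b = feats[, 3],
    class = rep(STAIN_LEVELS, each = n_per_class)
  ))
}

# Independent oracle: nearest class centroid in plain RGB space.
nearest_centroid_labels <- function(training_set) {
  feats <- as.matrix(training_set[, c("r", "g", "b")])
  cents <- do.call(rbind, lapply(split(as.data.frame(feats),
                                       training_set$class), colMeans))
  d2 <- sapply(seq_len(nrow(cents)), function(k) {
    rowSums(sweep(feats, 2, cents[k, ])^2)
  })
  stain_factor(rownames(cents)[max.col(-d2, ties.method = "first")])
}

# Exhaustive per-pixel ring assignment, the brute-force counterpart of
# build_ring_index().
brute_force_rings <- function(geometry, shape, ring_thickness_um) {
  ring_count <- ceiling(geometry$radius_um / ring_thickness_um)
  m <- matrix(NA_integer_, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      d <- sqrt((j - geometry$center_x)^2 + (i - geometry$center_y)^2) *
        geometry$pixel_size_um
      if (d <= geometry$radius_um) {
        m[i, j] <- as.integer(min(floor(d / ring_thickness_um),
                                  ring_count - 1))
      }
    }
  }
  m
}

random_label_map <- function(shape, seed) {
  withr::with_seed(seed,
    as_label_map(matrix(sample(1:3, prod(shape), replace = TRUE),
                        shape[1], shape[2])))
}

# A ring_profile tibble built directly from given per-ring fractions
# (for aggregation tests that bypass image profiling).
manual_profile <- function(frac_adipo, radius_um = 100, thickness_um = 25,
                           n_pixels = 1000) {
  rc <- length(frac_adipo)
  p <- tibble::tibble(
    ring = seq_len(rc) - 1L,
    r_inner_um = (seq_len(rc) - 1L) * thickness_um,
    r_outer_um = pmin(seq_len(rc) * thickness_um, radius_um),
    r_mid_um = (r_inner_um + r_outer_um) / 2,
    dist_wall_um = radius_um - r_mid_um,
    n_pixels = as.integer(rep(n_pixels, rc)),
    frac_adipogenic = frac_adipo,
    frac_osteogenic = (1 - frac_adipo) / 2,
    frac_negative = (1 - frac_adipo) / 2
  )
  structure(p, ring_thickness_um = thickness_um, radius_um = radius_um,
            class = c("ring_profile", class(p)))
}
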