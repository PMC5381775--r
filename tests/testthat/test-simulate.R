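test_that("zero noise produces class-mean colors and an exactly recoverable label map", {
  cm <- stain_color_model(sds = c(0, 0, 0), background_sd = 0)
  col <- simulate_colony(diameter_um = 100, color_model = cm, seed = 1)
  means <- cm$means
  inside <- !is.na(build_ring_index(col$geometry, dim(col$labels), 50))
  for (cls in 1:3) {
    px <- which(inside & unclass(col$labels) == cls)
    if (length(px) == 0) next
    expect_true(all(col$image[, , 1][px] == means[cls, 1]))
    expect_true(all(col$image[, , 2][px] == means[cls, 2]))
    expect_true(all(col$image[, , 3][px] == means[cls, 3]))
  }
  # a model trained on the three exact class colors recovers the ground
  # truth with zero errors (outside pixels are background-white = negative)
  ts <- as_training_set(data.frame(
    r = means[, 1], g = means[, 2], b = means[, 3], class = STAIN_LEVELS))
  model <- train_stain_classifier(ts)
  lm <- classify_image(model, col$image)
  expect_identical(unclass(lm)[inside], unclass(col$labels)[inside])
})

test_that("the same seed reproduces the colony bit for bit", {
  a <- simulate_colony(diameter_um = 120, seed = 99)
  b <- simulate_colony(diameter_um = 120, seed = 99)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- simulate_colony(diameter_um = 120, seed = 100)
  expect_false(identical(a$image, c$image))
})

test_that("a step layout places classes exactly by radius", {
  col <- simulate_colony(
    diameter_um = 200, seed = 5,
    layout = radial_layout(r_adipo_um = 50, r_osteo_um = 85))
  geo <- col$geometry
  h <- dim(col$labels)[1]; w <- dim(col$labels)[2]
  r_um <- sqrt((rep(seq_len(w), each = h) - geo$center_x)^2 +
               (rep(seq_len(h), times = w) - geo$center_y)^2) *
    geo$pixel_size_um
  labs <- as.vector(unclass(col$labels))
  expect_true(all(labs[r_um < 50] == 1L))
  expect_true(all(labs[r_um >= 50 & r_um < 85] == 2L))
  expect_true(all(labs[r_um >= 85 & r_um <= 100] == 3L))
  expect_true(all(labs[r_um > 100] == 3L)) # background is negative
})

test_that("per-zone class frequencies match specified mixtures within 3 binomial SDs", {
  probs <- rbind(c(0.7, 0.2, 0.1),
                 c(0.1, 0.8, 0.1),
                 c(0.1, 0.2, 0.7))
  col <- simulate_colony(
    diameter_um = 300, seed = 17,
    layout = radial_layout(r_adipo_um = 60, r_osteo_um = 120,
                           zone_probs = probs))
  geo <- col$geometry
  h <- dim(col$labels)[1]; w <- dim(col$labels)[2]
  r_um <- sqrt((rep(seq_len(w), each = h) - geo$center_x)^2 +
               (rep(seq_len(h), times = w) - geo$center_y)^2)
  labs <- as.vector(unclass(col$labels))
  zones <- list(r_um < 60, r_um >= 60 & r_um < 120,
                r_um >= 120 & r_um <= 150)
  for (z in 1:3) {
    n <- sum(zones[[z]])
    for (cls in 1:3) {
      p <- probs[z, cls]
      emp <- mean(labs[zones[[z]]] == cls)
      expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
    }
  }
})

test_that("training crops have the requested size, class purity and shading behavior", {
  crops <- simulate_training_crops(crop_size = 100, n_per_class = 1,
                                   seed = 2)
  expect_equal(nrow(crops), 3)
  expect_true(all(vapply(crops$image, function(i) prod(dim(i)[1:2]),
                         numeric(1)) == 10000))
  ts <- load_training_crops(crops)
  expect_equal(nrow(ts), 30000)
  expect_equal(unname(attr(ts, "per_class_counts")), rep(10000L, 3))

  # zero noise: crops are uniformly the class mean
  flat_cm <- stain_color_model(sds = c(0, 0, 0))
  uniform <- simulate_training_crops(flat_cm, crop_size = 4, seed = 3)
  img <- uniform$image[[1]]
  expect_true(all(img[, , 1] == 180 & img[, , 2] == 60 & img[, , 3] == 60))

  # shading: darkened pixels stay nearer their own shaded class mean than
  # any other class mean (class separation >> noise SD)
  shaded <- simulate_training_crops(crop_size = 20, shading = 0.5, seed = 4)
  cm <- stain_color_model()
  for (i in 1:3) {
    img <- shaded$image[[i]]
    dark <- matrix(as.integer(img[, 1:10, ]), ncol = 3)
    own_mean <- cm$means[i, ] * 0.5
    d_own <- rowSums(sweep(dark, 2, own_mean)^2)
    for (other in setdiff(1:3, i)) {
      d_other <- rowSums(sweep(dark, 2, cm$means[other, ])^2)
      expect_true(all(d_own < d_other))
    }
  }
})

test_that("invalid layouts are rejected", {
  expect_error(radial_layout(r_adipo_um = 80, r_osteo_um = 50), "radii")
  expect_error(radial_layout(r_adipo_um = 0, r_osteo_um = 50), "radii")
  expect_error(simulate_colony(diameter_um = 100, seed = 1,
                               layout = radial_layout(60, 90)),
               "exceed")
  expect_error(radial_layout(20, 40, zone_probs = matrix(1, 3, 3)))
})

test_that("logistic blend layouts give monotone radial class probabilities", {
  lay <- radial_layout(40, 80, kind = "logistic_blend", blend_um = 8)
  r <- seq(0, 100, by = 1)
  probs <- stainring:::layout_probs(lay, r, 100)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_true(all(diff(probs[, 1]) <= 1e-12))  # adipogenic falls with radius
  expect_true(all(diff(probs[, 3]) >= -1e-12)) # rim class rises with radius
})
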