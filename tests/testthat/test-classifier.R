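test_that("perfectly separable constant-color classes train to accuracy 1", {
  ts <- constant_training_set(100)
  model <- train_stain_classifier(ts)
  expect_equal(model$training_summary$accuracy, 1.0)
  expect_equal(model$training_summary$error_pixels, 0L)
  # a uniform pure-red image is labeled all-adipogenic
  red <- as_rgb_image(array(rep(c(255, 0, 0), each = 25), c(5, 5, 3)))
  expect_true(all(classify_image(model, red) == 1L))
})

test_that("well-separated Gaussian clusters reach >= 99% training accuracy and agree with a nearest-centroid oracle", {
  ts <- gaussian_training_set(n_per_class = 1000, sd = 10, seed = 42)
  model <- train_stain_classifier(ts)
  expect_gte(model$training_summary$accuracy, 0.99)
  svm_labels <- predict(model, ts)
  oracle_labels <- nearest_centroid_labels(ts)
  expect_gte(mean(svm_labels == oracle_labels), 0.99)
})

test_that("the in-package decision surface reproduces the underlying SVM fit", {
  ts <- gaussian_training_set(n_per_class = 200, sd = 10, seed = 5)
  model <- train_stain_classifier(ts)
  fit <- attr(model, "e1071_fit")
  grid <- as.matrix(expand.grid(r = seq(0, 255, by = 24),
                                g = seq(0, 255, by = 24),
                                b = seq(0, 255, by = 24)))
  mine <- as.character(predict(model, grid))
  theirs <- as.character(predict(fit, grid / 255))
  expect_gte(mean(mine == theirs), 0.999)
})

test_that("training and prediction are deterministic and pixel-independent", {
  ts <- gaussian_training_set(n_per_class = 300, sd = 10, seed = 9)
  m1 <- train_stain_classifier(ts)
  m2 <- train_stain_classifier(ts)
  col <- simulate_colony(diameter_um = 80, seed = 3)
  expect_identical(classify_image(m1, col$image),
                   classify_image(m1, col$image))
  expect_identical(classify_image(m1, col$image),
                   classify_image(m2, col$image))
  # permuting pixel positions then un-permuting labels changes nothing
  img <- col$image
  n <- prod(dim(img)[1:2])
  perm <- withr::with_seed(11, sample(n))
  flat <- matrix(as.integer(img), ncol = 3)
  shuffled <- as_rgb_image(array(flat[perm, ], c(n, 1, 3)))
  lab_perm <- as.integer(classify_image(m1, shuffled))
  unperm <- integer(n); unperm[perm] <- lab_perm
  expect_identical(unperm, as.vector(unclass(classify_image(m1, img))))
})

test_that("a serialized model predicts identically after reloading", {
  ts <- gaussian_training_set(n_per_class = 300, sd = 10, seed = 21)
  model <- train_stain_classifier(ts)
  path <- withr::local_tempfile(fileext = ".json")
  write_stain_classifier(model, path)
  restored <- read_stain_classifier(path)
  x <- withr::with_seed(2, matrix(sample(0:255, 3000, TRUE), 1000, 3))
  expect_identical(predict(model, x), predict(restored, x))
  expect_equal(restored$gamma, model$gamma)
  expect_equal(restored$training_summary$accuracy,
               model$training_summary$accuracy)
  expect_error(read_stain_classifier(withr::local_tempfile(lines = "{}",
                                                           fileext = ".json")),
               "not a stainring classifier")
})

test_that("degenerate and invalid training sets are handled", {
  expect_error(
    train_stain_classifier(data.frame(r = 1, g = 1, b = 1,
                                      class = "adipogenic")),
    "no reference crop|at least one"
  )
  dup <- data.frame(
    r = rep(c(10, 10, 200), each = 20), g = rep(c(10, 10, 200), each = 20),
    b = rep(c(10, 10, 200), each = 20),
    class = rep(STAIN_LEVELS, each = 20)
  )
  expect_warning(train_stain_classifier(dup), "identical feature sets")
})

test_that("every point of RGB space receives exactly one class", {
  ts <- constant_training_set(20)
  model <- train_stain_classifier(ts)
  x <- withr::with_seed(4, matrix(sample(0:255, 600, TRUE), 200, 3))
  labels <- predict(model, x)
  expect_false(anyNA(labels))
  expect_true(all(labels %in% STAIN_LEVELS))
})
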