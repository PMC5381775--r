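#' Train the three-class RGB pixel classifier
#'
#' Fits a support vector machine on (R, G, B) features to separate
#' adipogenic, osteogenic and stain-negative pixels. Channels are divided
#' by 255 so features lie in the unit cube before the kernel is applied;
#' the fitted decision surface is kept as plain arrays (support vectors,
#' dual coefficients, offsets) so the model serializes to a portable text
#' document and predicts identically before and after a round-trip.
#'
#' Multi-class prediction uses one-vs-one voting over the three pairwise
#' decision functions; vote ties are broken by the accumulated
#' decision-function margin, then by the lowest class code.
#'
#' @param training_set A `training_set` tibble from [load_training_crops()]
#'   or [as_training_set()]; at least one sample per class is required.
#' @param cost Regularization constant of the soft-margin SVM (default 1).
#' @param gamma Radial-basis kernel width. Default `NULL` applies the
#'   inverse-feature-count-times-variance heuristic
#'   `1 / (3 * var(scaled features))`.
#' @param kernel Kernel name; only `"radial"` and `"linear"` are supported.
#' @return A `stain_classifier` object.
#' @examples
#' ts <- as_training_set(data.frame(
#'   r = rep(c(255, 0, 255), each = 5),
#'   g = rep(c(0, 0, 255), each = 5),
#'   b = rep(c(0, 255, 255), each = 5),
#'   class = rep(c("adipogenic", "osteogenic", "negative"), each = 5)
#' ))
#' model <- train_stain_classifier(ts)
#' glance(model)
#' @export
train_stain_classifier <- function(training_set, cost = 1, gamma = NULL,
                                   kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  training_set <- as_training_set(training_set)
  counts <- table(training_set$class)
  if (any(counts == 0)) {
    stop("every class needs at least one training sample; missing: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  warn_identical_feature_sets(training_set)

  x <- as.matrix(training_set[, c("r", "g", "b")]) / 255
  y <- training_set$class
  if (is.null(gamma)) {
    v <- stats::var(as.vector(x))
    gamma <- if (isTRUE(v > 0)) 1 / (ncol(x) * v) else 1
  }
  fit <- e1071::svm(x = x, y = y, scale = FALSE, kernel = kernel,
                    cost = cost, gamma = gamma)

  # libsvm orders classes by first appearance; map back to canonical codes
  libsvm_codes <- match(fit$levels[fit$labels], STAIN_LEVELS)
  model <- structure(
    list(
      version = 1L,
      kernel = kernel,
      cost = cost,
      gamma = gamma,
      scale_divisor = 255,
      class_codes = as.integer(libsvm_codes),
      n_sv = as.integer(fit$nSV),
      sv = unname(as.matrix(fit$SV)),
      coefs = unname(as.matrix(fit$coefs)),
      rho = as.numeric(fit$rho),
      training_summary = list(
        n = nrow(training_set),
        per_class_counts = stats::setNames(as.integer(counts), names(counts))
      )
    ),
    class = "stain_classifier"
  )
  pred <- predict(model, training_set)
  acc <- mean(pred == y)
  model$training_summary$accuracy <- acc
  model$training_summary$error_pixels <- as.integer(round((1 - acc) * nrow(training_set)))
  attr(model, "e1071_fit") <- fit
  model
}

warn_identical_feature_sets <- function(training_set) {
  keys <- split(
    paste(training_set$r, training_set$g, training_set$b),
    training_set$class
  )
  keys <- lapply(keys, function(k) sort(unique(k)))
  pairs <- utils::combn(STAIN_LEVELS, 2, simplify = FALSE)
  for (p in pairs) {
    if (identical(keys[[p[1]]], keys[[p[2]]])) {
      warning("classes '", p[1], "' and '", p[2],
              "' share identical feature sets; training proceeds but the ",
              "boundary between them is arbitrary", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Predict stain classes for pixels or whole images
#'
#' @param object A `stain_classifier`.
#' @param newdata A data frame with columns `r`, `g`, `b` (0--255), an
#'   `rgb_image`, or an n x 3 matrix.
#' @param ... Unused.
#' @return A factor of class labels for tabular input; a `label_map` for an
#'   `rgb_image`.
#' @export
predict.stain_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "rgb_image")) {
    return(classify_image(object, newdata))
  }
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, c("r", "g", "b")])
  }
  stopifnot(is.matrix(newdata), ncol(newdata) == 3)
  codes <- predict_codes(object, newdata)
  stain_factor(codes)
}

# One-vs-one voting over the pairwise decision functions, margin then
# lowest-code tie-break. `x_raw` in 0..255 units. Returns integer codes.
predict_codes <- function(model, x_raw, chunk = 50000L) {
  n <- nrow(x_raw)
  out <- integer(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    out[lo:hi] <- predict_codes_block(model, x_raw[lo:hi, , drop = FALSE])
  }
  out
}

predict_codes_block <- function(model, x_raw) {
  x <- x_raw / model$scale_divisor
  k <- length(model$class_codes)
  kern <- kernel_matrix(model, x)
  start <- c(0L, cumsum(model$n_sv))
  votes <- matrix(0L, nrow(x), k)
  margin <- matrix(0, nrow(x), k)
  p <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      p <- p + 1L
      si <- (start[i] + 1L):start[i + 1L]
      sj <- (start[j] + 1L):start[j + 1L]
      dec <- kern[, si, drop = FALSE] %*% model$coefs[si, j - 1L] +
             kern[, sj, drop = FALSE] %*% model$coefs[sj, i] -
             model$rho[p]
      dec <- as.numeric(dec)
      win_i <- dec > 0
      votes[, i] <- votes[, i] + win_i
      votes[, j] <- votes[, j] + !win_i
      margin[, i] <- margin[, i] + dec
      margin[, j] <- margin[, j] - dec
    }
  }
  # deterministic argmax: votes, then margin, then lowest class code
  ord <- order(model$class_codes)
  codes <- model$class_codes[ord]
  votes <- votes[, ord, drop = FALSE]
  margin <- margin[, ord, drop = FALSE]
  best <- max.col(votes * 1e6 + pmin(pmax(margin, -1e5), 1e5),
                  ties.method = "first")
  codes[best]
}

kernel_matrix <- function(model, x) {
  sv <- model$sv
  if (model$kernel == "linear") {
    return(x %*% t(sv))
  }
  d2 <- outer(rowSums(x^2), rep(1, nrow(sv))) +
        outer(rep(1, nrow(x)), rowSums(sv^2)) -
        2 * (x %*% t(sv))
  exp(-model$gamma * pmax(d2, 0))
}

#' Classify every pixel of a micrograph
#'
#' Applies a trained classifier independently to each pixel's (R, G, B)
#' triple. Identical colors are classified once and the result broadcast,
#' so runtime scales with the number of distinct colors.
#'
#' @param model A `stain_classifier`.
#' @param image An `rgb_image` (or numeric H x W x 3 array, 0--255).
#' @return A `label_map` with the same height and width.
#' @export
classify_image <- function(model, image) {
  if (!inherits(image, "rgb_image")) image <- as_rgb_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  flat <- cbind(as.integer(image[, , 1]),
                as.integer(image[, , 2]),
                as.integer(image[, , 3]))
  key <- flat[, 1] * 65536L + flat[, 2] * 256L + flat[, 3]
  uidx <- which(!duplicated(key))
  ucodes <- predict_codes(model, flat[uidx, , drop = FALSE])
  codes <- ucodes[match(key, key[uidx])]
  as_label_map(matrix(codes, nrow = h, ncol = w))
}

#' @export
print.stain_classifier <- function(x, ...) {
  ts <- x$training_summary
  cat("<stain_classifier> ", x$kernel, " SVM on RGB/",
      x$scale_divisor, " features\n", sep = "")
  cat("  cost = ", format(x$cost), ", gamma = ", format(x$gamma),
      ", support vectors = ", nrow(x$sv), "\n", sep = "")
  if (!is.null(ts$accuracy)) {
    cat("  training: n = ", ts$n, ", accuracy = ",
        sprintf("%.4f", ts$accuracy), " (", ts$error_pixels,
        " misclassified)\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted stain classifier
#'
#' @param x A `stain_classifier`.
#' @param ... Unused.
#' @return One row per class: training sample count and support-vector
#'   count.
#' @method tidy stain_classifier
#' @export
tidy.stain_classifier <- function(x, ...) {
  counts <- x$training_summary$per_class_counts
  tibble::tibble(
    class = stain_factor(names(counts)),
    n_train = as.integer(counts),
    n_support = x$n_sv[match(match(names(counts), STAIN_LEVELS),
                             x$class_codes)]
  )
}

#' @rdname tidy.stain_classifier
#' @return `glance()`: a one-row tibble with hyperparameters, total sample
#'   count, training accuracy and misclassified-pixel count.
#' @method glance stain_classifier
#' @export
glance.stain_classifier <- function(x, ...) {
  ts <- x$training_summary
  tibble::tibble(
    kernel = x$kernel, cost = x$cost, gamma = x$gamma,
    n = ts$n, n_support = nrow(x$sv),
    accuracy = ts$accuracy, error_pixels = ts$error_pixels
  )
}
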