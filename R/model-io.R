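#' Save / load a stain classifier as a portable JSON document
#'
#' The model file is plain text: hyperparameters, the feature-scaling
#' convention, and the decision surface (support vectors, dual
#' coefficients, offsets) as numeric arrays, plus a mandatory `version`
#' field. Because prediction runs directly on these arrays, a deserialized
#' model yields bit-identical labels to the in-memory original.
#'
#' @param model A `stain_classifier`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_stain_classifier <- function(model, path) {
  stopifnot(inherits(model, "stain_classifier"))
  doc <- list(
    format = "stainring_classifier",
    version = model$version,
    kernel = model$kernel,
    cost = model$cost,
    gamma = model$gamma,
    scale_divisor = model$scale_divisor,
    class_codes = model$class_codes,
    n_sv = model$n_sv,
    sv = model$sv,
    coefs = model$coefs,
    rho = model$rho,
    training_summary = model$training_summary
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_stain_classifier
#' @return `read_stain_classifier()`: the restored `stain_classifier`.
#' @export
read_stain_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || !identical(doc$format, "stainring_classifier")) {
    stop("not a stainring classifier model file: ", path, call. = FALSE)
  }
  ts <- doc$training_summary
  ts$per_class_counts <- unlist(ts$per_class_counts)
  structure(
    list(
      version = as.integer(doc$version),
      kernel = doc$kernel,
      cost = doc$cost,
      gamma = doc$gamma,
      scale_divisor = doc$scale_divisor,
      class_codes = as.integer(doc$class_codes),
      n_sv = as.integer(doc$n_sv),
      sv = matrix(as.numeric(doc$sv), nrow = nrow(doc$sv)),
      coefs = matrix(as.numeric(doc$coefs), nrow = nrow(doc$coefs)),
      rho = as.numeric(doc$rho),
      training_summary = ts
    ),
    class = "stain_classifier"
  )
}
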