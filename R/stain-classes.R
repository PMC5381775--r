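#' The three stain classes
#'
#' The pipeline distinguishes three pixel classes in dual-chromogen-stained
#' micrographs: adipogenic areas (Oil Red O positive, red), osteogenic areas
#' (Fast Blue positive, blue), and stain-negative areas (undifferentiated
#' cells inside a confinement, background outside). Class codes are stable
#' integers used in label maps and serialized models.
#'
#' @return A tibble with one row per class: `code` (integer 1/2/3), `class`
#'   (factor label), and the default overlay color as `color_r`, `color_g`,
#'   `color_b` (0--255).
#' @examples
#' stain_classes()
#' @export
stain_classes <- function() {
  tibble::tibble(
    code = c(1L, 2L, 3L),
    class = stain_factor(c("adipogenic", "osteogenic", "negative")),
    color_r = c(255L, 0L, 255L),
    color_g = c(0L, 0L, 255L),
    color_b = c(0L, 255L, 255L)
  )
}

#' @rdname stain_classes
#' @format NULL
#' @export
STAIN_LEVELS <- c("adipogenic", "osteogenic", "negative")

#' Build a stain-class factor
#'
#' Coerces class labels (character names or integer codes 1--3) to a factor
#' with the canonical level order `adipogenic < osteogenic < negative`.
#'
#' @param x Character labels, integer codes, or a factor.
#' @return A factor with levels [STAIN_LEVELS].
#' @export
stain_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    stopifnot(all(x %in% 1:3))
    x <- STAIN_LEVELS[x]
  }
  bad <- setdiff(unique(x), STAIN_LEVELS)
  if (length(bad) > 0) {
    stop("unknown stain class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = STAIN_LEVELS)
}

#' Default red/blue/white overlay palette
#'
#' @return A 3x3 integer matrix (rows = classes in code order, columns =
#'   R, G, B channels, 0--255): red for adipogenic, blue for osteogenic,
#'   white for negative.
#' @export
stain_palette <- function() {
  cls <- stain_classes()
  pal <- as.matrix(cls[, c("color_r", "color_g", "color_b")])
  dimnames(pal) <- list(STAIN_LEVELS, c("r", "g", "b"))
  pal
}
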