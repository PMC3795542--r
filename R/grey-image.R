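#' Greyscale image container
#'
#' A `grey_image` is a numeric matrix of pixel intensities together with the
#' display range of the source modality (e.g. \[0, 255\] for 8-bit data).
#' All internal arithmetic is real-valued; quantization to integer grey
#' levels happens only when an image is written to disk.
#'
#' @param pixels Numeric matrix (rows = image rows, columns = image columns).
#' @param display_min,display_max Numeric display range bounds,
#'   `display_min < display_max`. Defaults 0 and 255 (8-bit).
#' @return An object of class `grey_image`.
#' @examples
#' img <- grey_image(matrix(0:24, 5, 5))
#' range(as.matrix(img))
#' @export
grey_image <- function(pixels, display_min = 0, display_max = 255) {
  if (is.grey_image(pixels)) {
    return(grey_image(unclass_pixels(pixels), display_min, display_max))
  }
  pixels <- as.matrix(pixels)
  pixels <- matrix(as.numeric(pixels), nrow(pixels), ncol(pixels))
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("a grey_image needs at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all pixel values must be finite", call. = FALSE)
  }
  if (!is.numeric(display_min) || !is.numeric(display_max) ||
      !(display_min < display_max)) {
    stop("display_min must be strictly less than display_max", call. = FALSE)
  }
  structure(pixels,
            display_min = as.numeric(display_min),
            display_max = as.numeric(display_max),
            class = c("grey_image", "matrix", "array"))
}

#' @rdname grey_image
#' @param x Object to test or convert.
#' @export
is.grey_image <- function(x) inherits(x, "grey_image")

#' @rdname grey_image
#' @param ... Unused.
#' @export
as.matrix.grey_image <- function(x, ...) unclass_pixels(x)

unclass_pixels <- function(x) {
  attr(x, "display_min") <- NULL
  attr(x, "display_max") <- NULL
  class(x) <- NULL
  x
}

#' @rdname grey_image
#' @export
display_range <- function(x) {
  stopifnot(is.grey_image(x))
  c(attr(x, "display_min"), attr(x, "display_max"))
}

# Rebuild a grey_image around new pixel data, keeping x's display range.
rewrap <- function(x, pixels) {
  rng <- display_range(x)
  grey_image(pixels, rng[1], rng[2])
}

# Accept either a bare matrix (assumed 8-bit range) or a grey_image.
as_grey_image <- function(x, display_min = 0, display_max = 255) {
  if (is.grey_image(x)) x else grey_image(x, display_min, display_max)
}

#' @export
print.grey_image <- function(x, ...) {
  rng <- display_range(x)
  cat(sprintf("grey_image: %d x %d pixels, display range [%g, %g], values [%g, %g]\n",
              nrow(x), ncol(x), rng[1], rng[2],
              min(x), max(x)))
  invisible(x)
}
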