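#' Flat greyscale morphology
#'
#' The four basic flat morphological operators. Dilation takes, at each
#' pixel, the maximum of the image over the (reflected) structuring-element
#' neighbourhood; erosion takes the minimum; opening is erosion followed by
#' dilation with the reflected element (the adjunction form, which makes
#' opening anti-extensive and idempotent even for asymmetric line elements);
#' closing is the dual composition. Samples that fall outside the frame are
#' supplied by edge replication, so monotone borders produce no spurious
#' top-hat residues.
#'
#' @param f A [grey_image] (a bare numeric matrix is accepted and treated as
#'   8-bit).
#' @param B A [make_structuring_element] object.
#' @return A [grey_image] of the same size and display range as `f`.
#' @examples
#' f <- grey_image(matrix(0, 5, 5) + diag(5) * 9)
#' B <- make_structuring_element("square", 3)
#' as.matrix(dilate(f, B))
#' @name morphology
NULL

# Shared core: max/min of f over pixel + offs (0-based row/col offsets).
minmax_filter <- function(f, offs, take_max) {
  minmax_filter_cpp(f, as.integer(offs[, 1]), as.integer(offs[, 2]), take_max)
}

#' @rdname morphology
#' @export
dilate <- function(f, B) {
  f <- as_grey_image(f)
  rewrap(f, minmax_filter(unclass_pixels(f), -se_offsets(B), TRUE))
}

#' @rdname morphology
#' @export
erode <- function(f, B) {
  f <- as_grey_image(f)
  rewrap(f, minmax_filter(unclass_pixels(f), se_offsets(B), FALSE))
}

#' @rdname morphology
#' @export
opening <- function(f, B) {
  f <- as_grey_image(f)
  px <- unclass_pixels(f)
  off <- se_offsets(B)
  # erosion with B, then its adjoint dilation (offsets negated): guarantees
  # anti-extensivity and idempotence even for asymmetric elements.
  rewrap(f, minmax_filter(minmax_filter(px, off, FALSE), -off, TRUE))
}

#' @rdname morphology
#' @export
closing <- function(f, B) {
  f <- as_grey_image(f)
  px <- unclass_pixels(f)
  off <- se_offsets(B)
  rewrap(f, minmax_filter(minmax_filter(px, -off, TRUE), off, FALSE))
}
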