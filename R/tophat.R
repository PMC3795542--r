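#' Top-hat transforms and the top-hat contrast operator
#'
#' The white top-hat (WTH) is the image minus its opening and extracts
#' bright structures smaller than the structuring element; the black
#' top-hat (BTH) is the closing minus the image and extracts dark
#' structures. Both are independent of the local background level, which is
#' what lets them pull low-contrast targets off an uneven background. When
#' a [rotation_set] is supplied the rotational ([rmp_opening()] /
#' [rmp_closing()]) forms are used; interpolated rotation branches can
#' overshoot the original by sub-quantum amounts, so negative residues are
#' clamped to zero to keep the extracted-structure images nonnegative.
#'
#' `tophat_contrast()` is the classical top-hat contrast operator:
#' `f + WTH - BTH`, brightening bright targets and darkening dark ones
#' simultaneously. Its output is deliberately not range-limited; the full
#' enhancement operator ([enhance_lambda()]) handles the display range.
#'
#' @param f A [grey_image] or numeric matrix.
#' @param B A [make_structuring_element] object.
#' @param R Optional [rotation_set]; omit (`NULL`) for the conventional
#'   single-orientation transforms.
#' @return A [grey_image] of the same size and display range as `f`.
#' @name tophat
NULL

#' @rdname tophat
#' @export
white_tophat <- function(f, B, R = NULL) {
  f <- as_grey_image(f)
  op <- if (is.null(R)) opening(f, B) else rmp_opening(f, B, R)
  rewrap(f, pmax(unclass_pixels(f) - unclass_pixels(op), 0))
}

#' @rdname tophat
#' @export
black_tophat <- function(f, B, R = NULL) {
  f <- as_grey_image(f)
  cl <- if (is.null(R)) closing(f, B) else rmp_closing(f, B, R)
  rewrap(f, pmax(unclass_pixels(cl) - unclass_pixels(f), 0))
}

#' @rdname tophat
#' @export
tophat_contrast <- function(f, B, R = NULL) {
  f <- as_grey_image(f)
  wth <- unclass_pixels(white_tophat(f, B, R))
  bth <- unclass_pixels(black_tophat(f, B, R))
  rewrap(f, unclass_pixels(f) + wth - bth)
}
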