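#' Rotational morphological opening and closing
#'
#' Isotropic morphological filtering with a single structuring element.
#' For each direction `theta_i` in the rotation set, the image is rotated
#' clockwise by `theta_i`, opened (or closed) with `B`, and rotated back
#' counterclockwise; the branch results are combined pixelwise by maximum
#' (opening) or minimum (closing). Combining over directions suppresses the
#' directional artefacts a single fixed-orientation structuring element
#' leaves at object peripheries. With `N = 1` both operators are identical
#' to the conventional [opening()] and [closing()].
#'
#' @param f A [grey_image] or numeric matrix.
#' @param B A [make_structuring_element] object.
#' @param R A [rotation_set]. Defaults to the recommended direction count
#'   for the shape of `B` (8 for disc/square, 36 for line).
#' @return A [grey_image] of the same size and display range as `f`.
#' @examples
#' f <- grey_image(matrix(runif(64, 0, 255), 8, 8))
#' B <- make_structuring_element("square", 3)
#' r1 <- rotation_set(1)
#' all.equal(as.matrix(rmp_opening(f, B, r1)), as.matrix(opening(f, B)))
#' @name rmp
NULL

rmp_combine <- function(f, B, R, op, combine) {
  f <- as_grey_image(f)
  if (is.null(R)) R <- rotation_set(default_n_rotations(B$shape))
  stopifnot(inherits(R, "rotation_set"))
  acc <- NULL
  for (th in R$angles) {
    branch <- if (th == 0) {
      unclass_pixels(op(f, B))
    } else {
      g <- rotate_image(f, th, "clockwise", R$interpolation)
      h <- rotate_image(op(g, B), th, "counterclockwise", R$interpolation)
      unclass_pixels(h)
    }
    acc <- if (is.null(acc)) branch else combine(acc, branch)
  }
  rewrap(f, acc)
}

#' @rdname rmp
#' @export
rmp_opening <- function(f, B, R = NULL) {
  rmp_combine(f, B, R, opening, pmax)
}

#' @rdname rmp
#' @export
rmp_closing <- function(f, B, R = NULL) {
  rmp_combine(f, B, R, closing, pmin)
}
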