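#' Image rotation about the frame centre
#'
#' Rotates an image about the geometric centre of its pixel grid,
#' `((H-1)/2, (W-1)/2)`, returning a same-size image. Output pixels whose
#' source location falls outside the frame are filled by edge replication
#' (the sampling location is clamped to the frame). With nearest-neighbour
#' interpolation and angles that are exact multiples of `pi/2`, rotation of
#' a square image is an exact pixel permutation.
#'
#' @param f A [grey_image] or numeric matrix.
#' @param angle Rotation angle in radians.
#' @param direction `"clockwise"` or `"counterclockwise"`.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return A [grey_image] of the same size and display range.
#' @export
rotate_image <- function(f, angle,
                         direction = c("clockwise", "counterclockwise"),
                         interpolation = c("bilinear", "nearest")) {
  f <- as_grey_image(f)
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  if (angle == 0) return(f)
  px <- unclass_pixels(f)
  H <- nrow(px); W <- ncol(px)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  # inverse mapping: the source offset is the output offset rotated by
  # -angle for a clockwise content rotation (and +angle for ccw)
  a <- if (direction == "clockwise") angle else -angle
  co <- cos(a); si <- sin(a)
  u <- (seq_len(H) - 1) - cy          # row offsets
  v <- (seq_len(W) - 1) - cx          # col offsets
  # src_row = co*u - si*v ; src_col = si*u + co*v  (about centre)
  sr <- outer(u * co, -v * si, "+") + cy
  sc <- outer(u * si, v * co, "+") + cx
  out <- if (interpolation == "nearest") {
    r0 <- clamp_idx(round(sr), H)
    c0 <- clamp_idx(round(sc), W)
    matrix(px[cbind(as.vector(r0) + 1L, as.vector(c0) + 1L)], H, W)
  } else {
    sr <- pmin(pmax(sr, 0), H - 1)
    sc <- pmin(pmax(sc, 0), W - 1)
    r0 <- floor(sr); c0 <- floor(sc)
    r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
    wr <- sr - r0; wc <- sc - c0
    g <- function(ri, ci) matrix(px[cbind(as.vector(ri) + 1L,
                                          as.vector(ci) + 1L)], H, W)
    (1 - wr) * (1 - wc) * g(r0, c0) + (1 - wr) * wc * g(r0, c1) +
      wr * (1 - wc) * g(r1, c0) + wr * wc * g(r1, c1)
  }
  rewrap(f, out)
}

clamp_idx <- function(i, n) {
  i <- pmin(pmax(i, 0), n - 1)
  matrix(as.integer(i), nrow(i), ncol(i))
}

#' Rotation direction set for rotational morphological processing
#'
#' The half circle (`pi` radians) is divided equally into `N` directions
#' `theta_i = pi * i / N`, `i = 0, ..., N-1`. With `N = 1` the set is the
#' single angle 0 and rotational processing reduces to the conventional
#' operators.
#'
#' @param N Positive integer number of directions. The recommended value is
#'   8 for disc or square structuring elements and 36 for line elements;
#'   see [default_n_rotations].
#' @param interpolation Interpolation used for the rotations: `"bilinear"`
#'   (default) or `"nearest"`.
#' @return An object of class `rotation_set`.
#' @export
rotation_set <- function(N, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  structure(list(N = N, angles = pi * (seq_len(N) - 1L) / N,
                 interpolation = interpolation),
            class = "rotation_set")
}

#' Recommended number of rotation directions for a structuring-element shape
#'
#' @param shape `"disc"`, `"square"` or `"line"`.
#' @return 8 for disc and square elements, 36 for line elements.
#' @export
default_n_rotations <- function(shape = c("disc", "square", "line")) {
  shape <- match.arg(shape)
  if (shape == "line") 36L else 8L
}

#' @export
print.rotation_set <- function(x, ...) {
  cat(sprintf("rotation_set: N = %d directions over [0, pi), %s interpolation\n",
              x$N, x$interpolation))
  invisible(x)
}
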