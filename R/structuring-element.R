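#' Flat structuring elements
#'
#' Builds the flat (binary) structuring element \eqn{B} that probes the image
#' in every morphological operation. Three shapes are supported:
#' `"disc"` (all lattice points within Euclidean distance
#' `(size - 1)/2` of the centre), `"square"` (a `size` by `size` block), and
#' `"line"` (a 1-pixel-wide Bresenham segment of `size` pixels through the
#' origin at a given angle). Disc and square sizes must be odd so the origin
#' is an unambiguous pixel centre.
#'
#' @param shape One of `"disc"`, `"square"`, `"line"`.
#' @param size Integer size parameter in pixels: disc diameter, square side,
#'   or line length. Must be >= 1; odd for disc and square.
#' @param angle Orientation of a line element in radians (row axis pointing
#'   down); only used when `shape == "line"`.
#' @return An object of class `struct_elem` with fields `mask` (logical
#'   matrix), `origin` (1-based row/col of the origin), `shape`, `size`,
#'   `angle`.
#' @examples
#' make_structuring_element("disc", 3)$mask
#' sum(make_structuring_element("disc", 31)$mask)
#' @export
make_structuring_element <- function(shape = c("disc", "square", "line"),
                                     size, angle = 0) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  if (is.na(size) || size < 1L) {
    stop("size must be an integer >= 1", call. = FALSE)
  }
  if (shape %in% c("disc", "square") && size %% 2L == 0L) {
    stop(sprintf("%s structuring elements must have odd size (got %d) so the origin is a pixel centre",
                 shape, size), call. = FALSE)
  }
  if (shape == "disc") {
    r <- (size - 1L) / 2
    off <- seq(-r, r)
    d2 <- outer(off^2, off^2, "+")
    mask <- d2 <= r^2 + 1e-9
    origin <- c(r + 1, r + 1)
  } else if (shape == "square") {
    mask <- matrix(TRUE, size, size)
    origin <- c((size + 1L) / 2, (size + 1L) / 2)
  } else {
    pts <- line_offsets(size, angle)
    rr <- range(pts[, 1]); cc <- range(pts[, 2])
    mask <- matrix(FALSE, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
    mask[cbind(pts[, 1] - rr[1] + 1L, pts[, 2] - cc[1] + 1L)] <- TRUE
    origin <- c(1L - rr[1], 1L - cc[1])
  }
  structure(list(mask = mask, origin = as.integer(origin),
                 shape = shape, size = size,
                 angle = if (shape == "line") angle else NA_real_),
            class = "struct_elem")
}

# Symmetric digital segment of `len` pixels through the origin, rasterized
# Bresenham-style along the dominant axis; round-half-away keeps the point
# set symmetric under 180-degree rotation.
line_offsets <- function(len, angle) {
  dy <- sin(angle); dx <- cos(angle)
  half <- (len - 1) / 2
  k <- seq(-half, half, by = 1)
  if (abs(dx) >= abs(dy)) {
    cs <- round_away(k)
    rs <- round_away(cs * dy / dx)
  } else {
    rs <- round_away(k)
    cs <- round_away(rs * dx / dy)
  }
  unique(cbind(as.integer(rs), as.integer(cs)))
}

round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("struct_elem: %s, size %d, %d x %d mask, %d active cells\n",
              x$shape, x$size, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

# 0-based (row, col) offsets of active cells relative to the origin.
se_offsets <- function(B) {
  stopifnot(inherits(B, "struct_elem"))
  idx <- which(B$mask, arr.ind = TRUE)
  cbind(idx[, 1] - B$origin[1], idx[, 2] - B$origin[2])
}

# 180-degree rotation of the SE about its origin (the reflected set B-check).
reflect_se <- function(B) {
  off <- -se_offsets(B)
  rr <- range(off[, 1]); cc <- range(off[, 2])
  mask <- matrix(FALSE, rr[2] - rr[1] + 1L, cc[2] - cc[1] + 1L)
  mask[cbind(off[, 1] - rr[1] + 1L, off[, 2] - cc[1] + 1L)] <- TRUE
  structure(list(mask = mask, origin = as.integer(c(1L - rr[1], 1L - cc[1])),
                 shape = B$shape, size = B$size, angle = B$angle),
            class = "struct_elem")
}
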