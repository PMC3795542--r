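#' Configuration for the contrast improvement ratio
#'
#' Window sizes for the local-contrast computation: `rc` is the side of the
#' square centre window and `rn` the side of the square neighbourhood
#' window (the surround is the annulus `rn`-window minus `rc`-window), both
#' centred on the evaluated pixel. `region` optionally restricts the
#' evaluation to a binary mask; by default every pixel where the `rn`
#' window fits inside the frame is evaluated.
#'
#' @param rc Odd integer, centre window side (default 11).
#' @param rn Odd integer, neighbourhood window side (default 41), `rn > rc`.
#' @param region Optional logical matrix (image-sized) restricting the
#'   evaluation region.
#' @return An object of class `cir_config`.
#' @export
cir_config <- function(rc = 11, rn = 41, region = NULL) {
  rc <- as.integer(rc); rn <- as.integer(rn)
  if (is.na(rc) || is.na(rn) || rc < 1L || rc >= rn ||
      rc %% 2L == 0L || rn %% 2L == 0L) {
    stop("rc and rn must be odd integers with 1 <= rc < rn", call. = FALSE)
  }
  if (!is.null(region)) region <- as.matrix(region) > 0
  structure(list(rc = rc, rn = rn, region = region), class = "cir_config")
}

# Integral-image sum of the (2h+1) x (2h+1) window around each pixel where
# the window fits; NA elsewhere.
box_sum <- function(px, h) {
  H <- nrow(px); W <- ncol(px)
  if (H < 2L * h + 1L || W < 2L * h + 1L) {
    stop("image is smaller than the window", call. = FALSE)
  }
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- t(apply(apply(px, 2L, cumsum), 1L, cumsum))
  out <- matrix(NA_real_, H, W)
  rows <- (h + 1L):(H - h); cols <- (h + 1L):(W - h)
  out[rows, cols] <- S[rows + h + 1L, cols + h + 1L, drop = FALSE] -
    S[rows - h, cols + h + 1L, drop = FALSE] -
    S[rows + h + 1L, cols - h, drop = FALSE] +
    S[rows - h, cols - h, drop = FALSE]
  out
}

#' Local contrast map
#'
#' At each pixel where the neighbourhood window fits inside the frame,
#' computes `C = |p - a| / (p + a)` where `p` is the mean intensity of the
#' `rc` x `rc` centre window and `a` the mean of the annulus (the
#' `rn` x `rn` window minus the centre window). Pixels with `p + a = 0`
#' get contrast 0; pixels where the window does not fit are 0 and excluded
#' from the default evaluation region of [cir()]. Values lie in `[0, 1]`.
#'
#' @param f A [grey_image] or numeric matrix.
#' @param cfg A [cir_config].
#' @return A [grey_image] with display range `[0, 1]`.
#' @export
local_contrast_map <- function(f, cfg = cir_config()) {
  f <- as_grey_image(f)
  grey_image(contrast_values(unclass_pixels(f), cfg)$C, 0, 1)
}

contrast_values <- function(px, cfg) {
  hc <- (cfg$rc - 1L) / 2L
  hn <- (cfg$rn - 1L) / 2L
  sc <- box_sum(px, hc)
  sn <- box_sum(px, hn)
  valid <- !is.na(sn)
  p <- sc / cfg$rc^2
  a <- (sn - sc) / (cfg$rn^2 - cfg$rc^2)
  C <- matrix(0, nrow(px), ncol(px))
  tot <- p + a
  ok <- valid & !is.na(tot) & tot > 0
  C[ok] <- abs(p[ok] - a[ok]) / tot[ok]
  list(C = C, valid = valid)
}

#' Contrast improvement ratio
#'
#' Quantifies the change in local contrast produced by an enhancement:
#' `CIR = sum((C - C~)^2) / sum(C^2)` over the evaluation region, where `C`
#' is the local contrast of the unenhanced image and `C~` that of the
#' enhanced image. The ratio is nonnegative and zero exactly when the two
#' contrast maps agree on the region; larger values indicate a stronger
#' change in target/surround separation.
#'
#' @param original,enhanced Same-size [grey_image]s or numeric matrices.
#' @param cfg A [cir_config].
#' @return A single nonnegative number.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 90, width = 90, seed = 1))
#' cir(ph$image, ph$image)  # 0: no change in contrast
#' @export
cir <- function(original, enhanced, cfg = cir_config()) {
  original <- as_grey_image(original)
  enhanced <- as_grey_image(enhanced)
  if (!all(dim(original) == dim(enhanced))) {
    stop("original and enhanced images must have the same size", call. = FALSE)
  }
  stopifnot(inherits(cfg, "cir_config"))
  co <- contrast_values(unclass_pixels(original), cfg)
  ce <- contrast_values(unclass_pixels(enhanced), cfg)
  region <- co$valid
  if (!is.null(cfg$region)) {
    if (!all(dim(cfg$region) == dim(original))) {
      stop("region mask must match the image size", call. = FALSE)
    }
    region <- region & cfg$region
  }
  denom <- sum(co$C[region]^2)
  if (denom == 0) {
    stop(errorCondition(
      "the original image has no local contrast on the evaluation region (CIR denominator is zero)",
      class = c("rmp_degenerate_error", "error", "condition")))
  }
  sum((co$C[region] - ce$C[region])^2) / denom
}
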