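#' Multiscale retinex baseline
#'
#' A reference global contrast-enhancement method: the weighted sum over
#' scales of the difference, in the logarithmic domain, between the image
#' and its Gaussian-blurred version,
#' `raw = sum_k w_k * (log(f + 1) - log(G_sigma_k * f + 1))`, followed by a
#' min-max linear stretch of the raw response to the display range. The
#' defaults are three scales with standard deviations 5, 15 and 25 pixels
#' and equal weights 1/3.
#'
#' @param f A [grey_image] or numeric matrix.
#' @param sigmas Gaussian surround standard deviations in pixels.
#' @param weights Scale weights; must match `sigmas` in length and sum to 1.
#' @return A [grey_image] spanning the display range (constant input maps
#'   to `display_min` via the degenerate-stretch rule).
#' @export
msr <- function(f, sigmas = c(5, 15, 25), weights = rep(1 / 3, 3)) {
  f <- as_grey_image(f)
  if (length(sigmas) != length(weights) || length(sigmas) < 1L) {
    stop("sigmas and weights must have equal length >= 1", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("weights must sum to 1", call. = FALSE)
  }
  px <- unclass_pixels(f)
  lg <- log(px + 1)
  raw <- 0
  for (k in seq_along(sigmas)) {
    blur <- gaussian_blur(px, sigmas[k])
    raw <- raw + weights[k] * (lg - log(blur + 1))
  }
  linear_stretch(rewrap(f, raw))
}

# Gaussian smoothing with replicated borders; kernel radius 3*sigma. Images
# smaller than the kernel are replicate-padded first (which leaves the
# result unchanged where no padding is needed) and cropped afterwards.
gaussian_blur <- function(px, sigma) {
  H <- nrow(px); W <- ncol(px)
  radius <- 2 * ceiling(3 * sigma) + 1
  pr <- max(0L, ceiling((radius - H) / 2))
  pc <- max(0L, ceiling((radius - W) / 2))
  if (pr > 0 || pc > 0) {
    ri <- pmin(pmax(seq(1L - pr, H + pr), 1L), H)
    ci <- pmin(pmax(seq(1L - pc, W + pc), 1L), W)
    padded <- EBImage::gblur(px[ri, ci, drop = FALSE], sigma = sigma,
                             boundary = "replicate")
    padded[(pr + 1L):(pr + H), (pc + 1L):(pc + W), drop = FALSE]
  } else {
    EBImage::gblur(px, sigma = sigma, boundary = "replicate")
  }
}

#' Contrast-limited adaptive histogram equalization baseline
#'
#' A reference local contrast-enhancement method. The image is tiled into
#' `block` x `block` pixel regions (edge tiles absorb the remainder); each
#' tile's histogram over `bins` levels of the display range is clipped at
#' `clip_limit` times the tile pixel count, the clipped excess is
#' redistributed uniformly over the bins, and the tile's equalization map
#' is built from the resulting CDF. Each pixel is remapped by bilinear
#' interpolation between the maps of the four nearest tile centres. In the
#' degenerate single-tile case with a large clip limit this reduces
#' exactly to global [histogram_equalize()].
#'
#' @param f A [grey_image] or numeric matrix.
#' @param block Tile side in pixels (default 9); must not exceed either
#'   image dimension.
#' @param clip_limit Histogram clip limit as a fraction of the tile pixel
#'   count (default 0.01).
#' @param bins Histogram levels (default 256).
#' @return A [grey_image] confined to the display range.
#' @export
clahe <- function(f, block = 9, clip_limit = 0.01, bins = 256) {
  f <- as_grey_image(f)
  block <- as.integer(block)
  if (is.na(block) || block < 2L) stop("block must be >= 2", call. = FALSE)
  if (clip_limit <= 0) stop("clip_limit must be positive", call. = FALSE)
  px <- unclass_pixels(f)
  H <- nrow(px); W <- ncol(px)
  if (block > H || block > W) {
    stop("block size exceeds the image dimensions", call. = FALSE)
  }
  rng <- display_range(f)
  bins <- as.integer(bins)
  lev <- pmin(pmax(floor((px - rng[1]) / (rng[2] - rng[1]) * bins), 0),
              bins - 1)
  nt_r <- max(1L, floor(H / block))
  nt_c <- max(1L, floor(W / block))
  # tile boundaries: equal blocks, last tile absorbs the remainder
  r_start <- (seq_len(nt_r) - 1L) * block + 1L
  r_end <- c(r_start[-1L] - 1L, H)
  c_start <- (seq_len(nt_c) - 1L) * block + 1L
  c_end <- c(c_start[-1L] - 1L, W)
  maps <- array(0, c(nt_r, nt_c, bins))
  for (i in seq_len(nt_r)) {
    for (j in seq_len(nt_c)) {
      tl <- lev[r_start[i]:r_end[i], c_start[j]:c_end[j]]
      n <- length(tl)
      h <- tabulate(as.vector(tl) + 1L, nbins = bins)
      clip <- clip_limit * n
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / bins
      maps[i, j, ] <- rng[1] + (rng[2] - rng[1]) * cumsum(h) / sum(h)
    }
  }
  # bilinear interpolation between tile-centre maps
  ctr_r <- (r_start + r_end) / 2
  ctr_c <- (c_start + c_end) / 2
  pos_r <- tile_coords(seq_len(H), ctr_r)
  pos_c <- tile_coords(seq_len(W), ctr_c)
  i0 <- matrix(pos_r$i0, H, W); i1 <- matrix(pos_r$i1, H, W)
  wr <- matrix(pos_r$w, H, W)
  j0 <- matrix(pos_c$i0, H, W, byrow = TRUE)
  j1 <- matrix(pos_c$i1, H, W, byrow = TRUE)
  wc <- matrix(pos_c$w, H, W, byrow = TRUE)
  lv <- as.vector(lev) + 1L
  g <- function(ii, jj) matrix(maps[cbind(as.vector(ii), as.vector(jj), lv)],
                               H, W)
  out <- (1 - wr) * (1 - wc) * g(i0, j0) + (1 - wr) * wc * g(i0, j1) +
    wr * (1 - wc) * g(i1, j0) + wr * wc * g(i1, j1)
  rewrap(f, out)
}

# For each pixel coordinate, the indices of the bracketing tile centres and
# the interpolation weight toward the upper one (clamped at the borders).
tile_coords <- function(coord, centres) {
  nt <- length(centres)
  i0 <- findInterval(coord, centres)
  i0 <- pmin(pmax(i0, 1L), max(nt - 1L, 1L))
  i1 <- pmin(i0 + 1L, nt)
  span <- centres[i1] - centres[i0]
  w <- ifelse(span > 0, (coord - centres[i0]) / span, 0)
  w <- pmin(pmax(w, 0), 1)
  list(i0 = i0, i1 = i1, w = w)
}
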