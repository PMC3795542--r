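#' Greyscale modification primitives
#'
#' `histogram_equalize()` remaps intensities through the image's empirical
#' cumulative distribution over `bins` levels spanning the display range:
#' `out = display_min + (display_max - display_min) * cdf(level)`. The map
#' is monotone non-decreasing; a constant image maps to `display_max`
#' (the CDF of the one occupied level is 1).
#'
#' `linear_stretch()` normalizes the occupied intensity range to the full
#' display range: `out = (g - min) * (display_max - display_min) /
#' (max - min) + display_min`. A constant image maps to `display_min`
#' (division guard for the degenerate range).
#'
#' `greyscale_modify()` is the two-stage modification applied to top-hat
#' images before recombination: equalization followed by stretching. A
#' featureless (constant, typically all-zero) top-hat image returns all
#' zeros so that it contributes nothing to the enhancement operator;
#' without this rule the constant-to-`display_max` equalization convention
#' would inject a global offset.
#'
#' @param g A [grey_image] or numeric matrix; for `greyscale_modify()` the
#'   pixels must be nonnegative (a top-hat image).
#' @param bins Number of histogram levels (default 256).
#' @return A [grey_image] with the same display range.
#' @name greyscale-modification
NULL

#' @rdname greyscale-modification
#' @export
histogram_equalize <- function(g, bins = 256) {
  g <- as_grey_image(g)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("bins must be >= 2", call. = FALSE)
  rng <- display_range(g)
  px <- unclass_pixels(g)
  lev <- pmin(pmax(floor((px - rng[1]) / (rng[2] - rng[1]) * bins), 0), bins - 1)
  counts <- tabulate(as.vector(lev) + 1L, nbins = bins)
  cdf <- cumsum(counts) / length(px)
  rewrap(g, matrix(rng[1] + (rng[2] - rng[1]) * cdf[as.vector(lev) + 1L],
                   nrow(px), ncol(px)))
}

#' @rdname greyscale-modification
#' @export
linear_stretch <- function(g) {
  g <- as_grey_image(g)
  rng <- display_range(g)
  px <- unclass_pixels(g)
  mn <- min(px); mx <- max(px)
  if (mx - mn <= 0) {
    return(rewrap(g, matrix(rng[1], nrow(px), ncol(px))))
  }
  rewrap(g, (px - mn) * (rng[2] - rng[1]) / (mx - mn) + rng[1])
}

#' @rdname greyscale-modification
#' @export
greyscale_modify <- function(g, bins = 256) {
  g <- as_grey_image(g)
  px <- unclass_pixels(g)
  if (any(px < 0)) {
    stop("greyscale_modify expects a nonnegative (top-hat) image", call. = FALSE)
  }
  if (max(px) - min(px) <= 0) {
    # featureless top-hat: must contribute nothing downstream
    return(rewrap(g, matrix(0, nrow(px), ncol(px))))
  }
  linear_stretch(histogram_equalize(g, bins))
}

#' Configuration for the full enhancement operator
#'
#' Collects the tunable parameters of [enhance_lambda()]. Defaults follow
#' the method's reference settings: a disc structuring element of diameter
#' 31 pixels, 8 rotation directions for disc/square (36 for line), 8-bit
#' output range, no pre-smoothing, 256 histogram bins.
#'
#' @param se_shape Structuring-element shape: `"disc"`, `"square"`, `"line"`.
#' @param se_size Structuring-element size in pixels (odd, >= 3 for
#'   disc/square); default 31.
#' @param n_rot Number of rotation directions, or `NULL` to auto-select by
#'   shape (8 for disc/square, 36 for line).
#' @param out_min,out_max Output display range (default 0, 255).
#' @param presmooth Logical; if `TRUE` the input is first smoothed by a
#'   rotational opening followed by a rotational closing with a small disc
#'   (`presmooth_size`), an edge-preserving noise reduction applied before
#'   enhancement so noise is not amplified.
#' @param presmooth_size Diameter of the pre-smoothing disc (default 3).
#' @param hist_bins Histogram bins for the greyscale modification.
#' @param interpolation Rotation interpolation, `"bilinear"` or `"nearest"`.
#' @param range_mode How the recombined output is restricted to
#'   `[out_min, out_max]`: `"clip"` (saturation, the default — preserves the
#'   absolute enhancement of mid-range structures) or `"rescale"`
#'   (min-max linear stretch).
#' @param se_angle Line-element orientation in radians (line shape only).
#' @return An object of class `enhance_config`.
#' @export
enhance_config <- function(se_shape = c("disc", "square", "line"),
                           se_size = 31, n_rot = NULL,
                           out_min = 0, out_max = 255,
                           presmooth = FALSE, presmooth_size = 3,
                           hist_bins = 256,
                           interpolation = c("bilinear", "nearest"),
                           range_mode = c("clip", "rescale"),
                           se_angle = 0) {
  se_shape <- match.arg(se_shape)
  interpolation <- match.arg(interpolation)
  range_mode <- match.arg(range_mode)
  se_size <- as.integer(se_size)
  if (se_shape %in% c("disc", "square") &&
      (se_size < 3L || se_size %% 2L == 0L)) {
    stop("se_size must be odd and >= 3 for disc/square elements", call. = FALSE)
  }
  if (is.null(n_rot)) n_rot <- default_n_rotations(se_shape)
  n_rot <- as.integer(n_rot)
  if (n_rot < 1L) stop("n_rot must be >= 1", call. = FALSE)
  if (!(out_min < out_max)) stop("out_min must be < out_max", call. = FALSE)
  structure(list(se_shape = se_shape, se_size = se_size, se_angle = se_angle,
                 n_rot = n_rot, out_min = out_min, out_max = out_max,
                 presmooth = presmooth,
                 presmooth_size = as.integer(presmooth_size),
                 hist_bins = as.integer(hist_bins),
                 interpolation = interpolation, range_mode = range_mode),
            class = "enhance_config")
}

#' @export
print.enhance_config <- function(x, ...) {
  cat(sprintf(paste0("enhance_config: %s SE size %d, N = %d rotations, ",
                     "range [%g, %g] (%s), presmooth = %s\n"),
              x$se_shape, x$se_size, x$n_rot, x$out_min, x$out_max,
              x$range_mode, x$presmooth))
  invisible(x)
}

#' Full rotational top-hat contrast enhancement
#'
#' The complete enhancement operator: rotational white and black top-hats
#' are computed with the configured structuring element and direction
#' count, each top-hat image is greyscale-modified (histogram equalization
#' then linear stretching, [greyscale_modify()]), and the results are
#' recombined as `f + nu_WTH - nu_BTH`. The recombined image is restricted
#' to the configured output range by saturation clipping (or min-max
#' rescaling if `range_mode = "rescale"`). With `presmooth = TRUE` the
#' input is first denoised by a rotational opening followed by a rotational
#' closing with a small disc.
#'
#' @param f A [grey_image] or numeric matrix (treated as 8-bit).
#' @param cfg An [enhance_config]; defaults to the reference settings.
#' @return A [grey_image] with display range `[out_min, out_max]`.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 1))
#' enh <- enhance_lambda(ph$image, enhance_config(se_size = 15))
#' range(as.matrix(enh))
#' @export
enhance_lambda <- function(f, cfg = enhance_config()) {
  f <- as_grey_image(f)
  stopifnot(inherits(cfg, "enhance_config"))
  B <- make_structuring_element(cfg$se_shape, cfg$se_size, cfg$se_angle)
  R <- rotation_set(cfg$n_rot, cfg$interpolation)
  if (isTRUE(cfg$presmooth)) {
    Bs <- make_structuring_element("disc", cfg$presmooth_size)
    f <- rmp_closing(rmp_opening(f, Bs, R), Bs, R)
  }
  wth <- white_tophat(f, B, R)
  bth <- black_tophat(f, B, R)
  nu_w <- unclass_pixels(greyscale_modify(wth, cfg$hist_bins))
  nu_b <- unclass_pixels(greyscale_modify(bth, cfg$hist_bins))
  lam <- unclass_pixels(f) + nu_w - nu_b
  out <- if (cfg$range_mode == "clip") {
    pmin(pmax(lam, cfg$out_min), cfg$out_max)
  } else {
    unclass_pixels(linear_stretch(grey_image(lam, cfg$out_min, cfg$out_max)))
  }
  grey_image(out, cfg$out_min, cfg$out_max)
}
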