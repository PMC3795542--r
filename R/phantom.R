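#' Synthetic low-contrast phantom specification
#'
#' Describes a test phantom emulating the kind of image the enhancement
#' method targets: several low-contrast bright blobs of differing mean
#' intensity on a spatially uneven background, with optional additive
#' Gaussian noise. The default is a 218 x 238 pixel 8-bit frame with six
#' flat-disc blobs (radii 10-15 px, amplitudes 10-30 grey levels) on a base
#' level of 100 with a left-to-right linear ramp of 40 levels and noise
#' standard deviation 2. Blob amplitudes are kept below 20% of the display
#' range so the targets sit in the low-contrast regime where enhancement is
#' meaningful.
#'
#' @param height,width Frame size in pixels (default 218 x 238).
#' @param blobs Data frame with columns `row`, `col`, `radius`, `amplitude`
#'   (one row per blob). Every blob must lie fully inside the frame.
#' @param base Background base level (default 100).
#' @param gradient Length-2 numeric: total intensity rise across the frame
#'   in the row and column directions (default `c(0, 40)`, a left-to-right
#'   ramp).
#' @param modulation_amp Amplitude of an optional low-frequency sinusoidal
#'   background modulation (default 0).
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (default 2).
#' @param seed Integer seed for the noise (default 1).
#' @param display_min,display_max Display range (default 0, 255).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 218, width = 238, blobs = NULL,
                         base = 100, gradient = c(0, 40),
                         modulation_amp = 0, noise_sigma = 2, seed = 1,
                         display_min = 0, display_max = 255) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L) stop("invalid frame size", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (is.null(blobs)) blobs <- default_blobs(height, width)
  blobs <- as.data.frame(blobs)
  need <- c("row", "col", "radius", "amplitude")
  if (!all(need %in% names(blobs))) {
    stop("blobs needs columns row, col, radius, amplitude", call. = FALSE)
  }
  if (nrow(blobs) > 0) {
    inside <- blobs$row - blobs$radius >= 1 & blobs$row + blobs$radius <= height &
      blobs$col - blobs$radius >= 1 & blobs$col + blobs$radius <= width
    if (!all(inside)) {
      stop("every blob must lie fully inside the frame", call. = FALSE)
    }
  }
  structure(list(height = height, width = width, blobs = blobs, base = base,
                 gradient = as.numeric(gradient),
                 modulation_amp = modulation_amp, noise_sigma = noise_sigma,
                 seed = seed, display_min = display_min,
                 display_max = display_max),
            class = "phantom_spec")
}

# Six low-contrast targets spread over the frame; positions are scaled to
# the frame so small phantoms remain valid. All base diameters stay below
# the default 31-pixel structuring-element diameter.
default_blobs <- function(height, width) {
  fr <- c(0.28, 0.25, 0.30, 0.70, 0.72, 0.68)
  fc <- c(0.20, 0.52, 0.84, 0.22, 0.50, 0.82)
  radius <- c(12, 15, 10, 14, 11, 13)
  amplitude <- c(30, 20, 25, 15, 10, 22)
  scale <- min(height, width) / 218
  if (scale < 1) radius <- pmax(3, round(radius * scale))
  data.frame(row = round(fr * height), col = round(fc * width),
             radius = radius, amplitude = amplitude)
}

#' Generate a synthetic phantom image
#'
#' Renders the phantom described by a [phantom_spec]: background plane plus
#' linear ramp plus optional sinusoidal modulation, flat-disc bright blobs,
#' and seeded additive Gaussian noise, clipped to the display range. Also
#' returns the binary mask of blob supports so contrast metrics can be
#' restricted to the targets. Identical specs (including seed) produce
#' bit-identical output.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `image` (a [grey_image]), `mask` (logical
#'   matrix of blob supports) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(height = 80, width = 100, seed = 7))
#' ph$image
#' sum(ph$mask)
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  rowfrac <- if (H > 1) (seq_len(H) - 1) / (H - 1) else rep(0, H)
  colfrac <- if (W > 1) (seq_len(W) - 1) / (W - 1) else rep(0, W)
  px <- spec$base + outer(spec$gradient[1] * rowfrac,
                          spec$gradient[2] * colfrac, "+")
  if (spec$modulation_amp != 0) {
    px <- px + spec$modulation_amp *
      outer(sin(2 * pi * rowfrac), sin(2 * pi * colfrac))
  }
  mask <- matrix(FALSE, H, W)
  if (nrow(spec$blobs) > 0) {
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    for (k in seq_len(nrow(spec$blobs))) {
      b <- spec$blobs[k, ]
      inside <- (rr - b$row)^2 + (cc - b$col)^2 <= b$radius^2
      px[inside] <- px[inside] + b$amplitude
      mask <- mask | inside
    }
  }
  if (spec$noise_sigma > 0) {
    px <- px + with_local_seed(spec$seed,
                               matrix(stats::rnorm(H * W, 0, spec$noise_sigma),
                                      H, W))
  }
  px <- pmin(pmax(px, spec$display_min), spec$display_max)
  list(image = grey_image(px, spec$display_min, spec$display_max),
       mask = mask, spec = spec)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("phantom_spec: %d x %d, %d blobs, base %g, gradient ",
                     "(%g, %g), noise sd %g, seed %s\n"),
              x$height, x$width, nrow(x$blobs), x$base, x$gradient[1],
              x$gradient[2], x$noise_sigma, format(x$seed)))
  invisible(x)
}
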