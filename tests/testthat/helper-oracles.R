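# Naive reference implementations, independent of the package's kernels.

clamp1 <- function(i, n) pmin(pmax(i, 1L), n)

# Brute-force min/max filter: for each pixel, gather f over the given
# 0-based offsets (row, col) with edge-replicate clamping.
naive_minmax <- function(px, off, take_max) {
  H <- nrow(px); W <- ncol(px)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    rr <- clamp1(r + off[, 1], H)
    for (c in seq_len(W)) {
      v <- px[cbind(rr, clamp1(c + off[, 2], W))]
      out[r, c] <- if (take_max) max(v) else min(v)
    }
  }
  out
}

se_off <- function(B) {
  idx <- which(B$mask, arr.ind = TRUE)
  cbind(idx[, 1] - B$origin[1], idx[, 2] - B$origin[2])
}

# Dilation samples f(p - b), erosion f(p + b), b the SE offsets.
naive_dilate <- function(px, B) naive_minmax(px, -se_off(B), TRUE)
naive_erode <- function(px, B) naive_minmax(px, se_off(B), FALSE)
naive_opening <- function(px, B) naive_minmax(naive_erode(px, B), -se_off(B), TRUE)
naive_closing <- function(px, B) naive_minmax(naive_dilate(px, B), se_off(B), FALSE)

# Exact 90-degree rotations of a square matrix by index remapping.
# k quarter-turns counterclockwise in the usual matrix-display sense.
rot90_ccw <- function(m, k = 1) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m)[nrow(t(m)):1, , drop = FALSE]
  m
}

random_image <- function(h, w, maxv = 255) {
  matrix(sample(0:maxv, h * w, replace = TRUE), h, w)
}

# Nested-loop windowed mean for the local-contrast oracle (only at pixels
# where the window fits; NA elsewhere).
naive_box_mean <- function(px, side) {
  h <- (side - 1) / 2
  H <- nrow(px); W <- ncol(px)
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (r - h >= 1 && r + h <= H && c - h >= 1 && c + h <= W) {
        out[r, c] <- mean(px[(r - h):(r + h), (c - h):(c + h)])
      }
    }
  }
  out
}

naive_contrast <- function(px, rc, rn) {
  p <- naive_box_mean(px, rc)
  hn <- (rn - 1) / 2
  H <- nrow(px); W <- ncol(px)
  C <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (r - hn >= 1 && r + hn <= H && c - hn >= 1 && c + hn <= W) {
        full <- sum(px[(r - hn):(r + hn), (c - hn):(c + hn)])
        ctr <- p[r, c] * rc^2
        a <- (full - ctr) / (rn^2 - rc^2)
        tot <- p[r, c] + a
        C[r, c] <- if (tot > 0) abs(p[r, c] - a) / tot else 0
      }
    }
  }
  C
}

naive_cir <- function(orig, enh, rc, rn) {
  C <- naive_contrast(orig, rc, rn)
  Ct <- naive_contrast(enh, rc, rn)
  ok <- !is.na(C)
  sum((C[ok] - Ct[ok])^2) / sum(C[ok]^2)
}
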