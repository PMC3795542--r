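#' Read a greyscale image
#'
#' Reads an 8- or 16-bit single-channel image from PNG, TIFF or PGM. The
#' display range is inferred from the file's bit depth ([0, 255] or
#' [0, 65535]); pixel values are returned on that scale as real numbers.
#' Multi-channel files are rejected unless `collapse = TRUE`, in which case
#' channels are averaged.
#'
#' @param path Path to the image file.
#' @param collapse Average the channels of a multi-channel file instead of
#'   rejecting it.
#' @return A [grey_image].
#' @export
read_image <- function(path, collapse = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    depth <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(arr, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else if (ext == "pgm") {
    return(read_pgm(path))
  } else {
    stop("unsupported format '", ext, "'; supported formats: PNG, TIFF, PGM",
         call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1L]
    } else if (collapse) {
      arr <- apply(arr, c(1L, 2L), mean)
    } else {
      stop("multi-channel image; pass collapse = TRUE to average channels",
           call. = FALSE)
    }
  }
  maxval <- 2^depth - 1
  grey_image(arr * maxval, 0, maxval)
}

# Bit depth lives in byte 25 (0-based 24) of a PNG stream: IHDR data starts
# after the 8-byte signature plus the 8-byte chunk header.
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) stop("truncated PNG file", call. = FALSE)
  as.integer(hdr[25L])
}

#' Write a greyscale image
#'
#' Quantizes (round half away from zero, then clip to the display range)
#' and writes to a lossless format chosen by the file extension: PNG
#' (8-bit), TIFF (8- or 16-bit) or PGM (plain-text P2, 8- or 16-bit).
#' Integral in-range images round-trip exactly.
#'
#' @param img A [grey_image] (or numeric matrix treated as 8-bit).
#' @param path Output path; extension selects the format.
#' @param bitdepth 8 or 16; default inferred from the display range.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bitdepth = NULL) {
  img <- as_grey_image(img)
  rng <- display_range(img)
  if (is.null(bitdepth)) bitdepth <- if (rng[2] > 255) 16L else 8L
  bitdepth <- as.integer(bitdepth)
  if (!bitdepth %in% c(8L, 16L)) stop("bitdepth must be 8 or 16", call. = FALSE)
  maxval <- 2^bitdepth - 1
  q <- quantize(unclass_pixels(img), rng[1], rng[2])
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    stop("lossy formats are not supported; use PNG, TIFF or PGM", call. = FALSE)
  }
  if (ext == "png") {
    if (bitdepth != 8L) {
      stop("PNG output is 8-bit only; use TIFF or PGM for 16-bit", call. = FALSE)
    }
    png::writePNG(q / maxval, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q / maxval, path, bits.per.sample = bitdepth,
                    compression = "none")
  } else if (ext == "pgm") {
    write_pgm(q, path, maxval)
  } else {
    stop("unsupported format '", ext, "'; supported formats: PNG, TIFF, PGM",
         call. = FALSE)
  }
  invisible(path)
}

# round half away from zero, clip to the display range
quantize <- function(px, lo, hi) {
  pmin(pmax(sign(px) * floor(abs(px) + 0.5), lo), hi)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (expected P2 or P5 header)", call. = FALSE)
  }
  if (magic == "P2") {
    close(con); on.exit()
    txt <- sub("#.*$", "", readLines(path, warn = FALSE))
    vals <- scan(text = paste(txt[-1L], collapse = " "), what = integer(),
                 quiet = TRUE)
    W <- vals[1]; H <- vals[2]; maxval <- vals[3]
    if (length(vals) < 3 + W * H) stop("truncated PGM file", call. = FALSE)
    px <- matrix(vals[4:(3 + W * H)], H, W, byrow = TRUE)
  } else {
    head <- pgm_header_ints(con, 3L)
    W <- head[1]; H <- head[2]; maxval <- head[3]
    px <- if (maxval < 256) {
      matrix(as.integer(readBin(con, "raw", W * H)), H, W, byrow = TRUE)
    } else {
      v <- readBin(con, "integer", W * H, size = 2L, signed = FALSE,
                   endian = "big")
      matrix(v, H, W, byrow = TRUE)
    }
  }
  grey_image(px, 0, maxval)
}

# read `n` whitespace-separated integers, skipping '#' comments, leaving the
# connection positioned just past the single whitespace after the last one
pgm_header_ints <- function(con, n) {
  out <- integer(0)
  tok <- ""
  in_comment <- FALSE
  while (length(out) < n) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header", call. = FALSE)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
    } else if (ch == "#") {
      in_comment <- TRUE
    } else if (grepl("[0-9]", ch)) {
      tok <- paste0(tok, ch)
    } else if (nzchar(tok)) {
      out <- c(out, as.integer(tok))
      tok <- ""
    }
  }
  out
}

write_pgm <- function(q, path, maxval) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = min(ncol(q), 16L))
  invisible(path)
}
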