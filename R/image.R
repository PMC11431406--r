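#' Validate an integer intensity image
#'
#' Images are plain integer matrices (grayscale) or `M x N x 3` arrays
#' (red, green, blue), with every value an integer in `[0, L-1]`.
#' Higher bit depths are rejected rather than rescaled: rescaling would
#' silently change the histogram and hence every entropy downstream.
#'
#' @param image Numeric matrix or 3-channel array of integer intensities.
#' @param L Number of gray levels (default 256, i.e. 8-bit).
#' @return The image, invisibly, after validation.
#' @export
validate_image <- function(image, L = 256) {
  if (!is.numeric(image)) abort("`image` must be numeric.")
  d <- dim(image)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L)))) {
    abort("`image` must be an M x N matrix or an M x N x 3 array.")
  }
  if (length(image) == 0L) abort("`image` is empty.")
  if (anyNA(image)) abort("`image` contains missing values.")
  if (any(image != round(image))) abort("`image` intensities must be integers.")
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > L - 1) {
    abort(sprintf(
      "Pixel values outside [0, %d]: observed range [%s, %s]. For deeper bit depths pass an explicit `L`.",
      L - 1, format(rng[1]), format(rng[2])
    ))
  }
  invisible(image)
}

is_color_image <- function(image) length(dim(image)) == 3L && dim(image)[3] == 3L

#' Split a color image into red, green and blue channel images
#'
#' Color images are never collapsed to luminance anywhere in the package;
#' per-channel processing is the only color path.
#'
#' @inheritParams validate_image
#' @return Named list of three matrices: `red`, `green`, `blue`.
#' @examples
#' img <- array(c(10, 20, 30), dim = c(1, 1, 3))
#' split_channels(img)
#' @export
split_channels <- function(image, L = 256) {
  validate_image(image, L)
  if (!is_color_image(image)) {
    abort("`image` has a single channel; skip splitting and process it directly.")
  }
  chan <- function(k) {
    ch <- image[, , k]
    if (!is.matrix(ch)) dim(ch) <- dim(image)[1:2]   # keep 1 x N shapes
    ch
  }
  list(red = chan(1), green = chan(2), blue = chan(3))
}

#' Stack three channel images back into a color image
#'
#' Inverse of [split_channels()].
#'
#' @param red,green,blue Matrices of identical dimension.
#' @return An `M x N x 3` array.
#' @export
stack_channels <- function(red, green, blue) {
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    abort("Channel dimensions differ.")
  }
  array(c(red, green, blue), dim = c(dim(red), 3L))
}

#' Read a raster image as integer intensities
#'
#' Reads PNG, TIFF and PNM (PGM/PPM, both ASCII and binary) files into an
#' integer matrix (gray) or `M x N x 3` array (color).  An alpha channel,
#' if present, is dropped.  Inputs deeper than 8 bits are rejected with a
#' message unless an explicit `L` is supplied.
#'
#' @param path File path; format chosen by extension
#'   (`.png`, `.tif`/`.tiff`, `.pgm`/`.ppm`/`.pnm`).
#' @param L Gray-level count the intensities are encoded against.
#' @return Integer matrix or array with values in `[0, L-1]`.
#' @export
read_image <- function(path, L = 256) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    img <- decode_unit_raster(x, L)
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path)
    img <- decode_unit_raster(x, L)
  } else if (ext %in% c("pgm", "ppm", "pnm")) {
    img <- read_pnm(path, L)
  } else {
    abort(sprintf("Unsupported image extension '%s' (use png/tiff/pgm/ppm).", ext))
  }
  validate_image(img, L)
  img
}

# png/tiff decoders hand back doubles in [0, 1]; map back to integer levels.
decode_unit_raster <- function(x, L) {
  d <- dim(x)
  if (length(d) == 3L && d[3] %in% c(2L, 4L)) {            # drop alpha
    x <- if (d[3] == 2L) x[, , 1] else x[, , 1:3]
    d <- dim(x)
  }
  v <- x * (L - 1)
  if (max(abs(v - round(v))) > 1e-6) {
    abort(paste0(
      "Image does not decode to integer levels at L = ", L,
      "; it likely has a deeper bit depth. Pass the matching `L` explicitly."
    ))
  }
  r <- round(v)
  storage.mode(r) <- "integer"
  if (length(d) == 3L && d[3] == 1L) r <- r[, , 1]
  r
}

#' Write a grayscale or color image to PNG
#'
#' @inheritParams validate_image
#' @param path Output file path.
#' @export
write_image_png <- function(image, path, L = 256) {
  validate_image(image, L)
  png::writePNG(image / (L - 1), path)
  invisible(path)
}

# Minimal PNM reader: P2/P5 (gray), P3/P6 (color), maxval up to 255 unless
# the caller passes a larger L.
read_pnm <- function(path, L = 256) {
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  n_raw <- length(raw)
  read_token <- function() {
    # skip whitespace and '#' comments
    repeat {
      while (pos <= n_raw && raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d))) pos <<- pos + 1L
      if (pos <= n_raw && raw[pos] == as.raw(0x23)) {
        while (pos <= n_raw && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n_raw && !(raw[pos] %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d)))) pos <<- pos + 1L
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) abort("Not a supported PNM file (P2/P3/P5/P6).")
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (maxval > L - 1) {
    abort(sprintf("PNM maxval %d exceeds L-1 = %d; pass an explicit `L`.", maxval, L - 1))
  }
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n_vals <- width * height * channels
  if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L                                        # single whitespace after maxval
    vals <- as.integer(raw[pos:(pos + n_vals - 1L)])
  } else {
    vals <- as.integer(vapply(seq_len(n_vals), function(i) read_token(), ""))
  }
  # PNM is row-major, R arrays column-major
  if (channels == 1L) {
    t(matrix(vals, nrow = width, ncol = height))
  } else {
    px <- matrix(vals, nrow = 3L)
    arr <- array(0L, dim = c(height, width, 3L))
    for (ch in 1:3) arr[, , ch] <- t(matrix(px[ch, ], nrow = width))
    arr
  }
}

#' Write a grayscale image as binary PGM (P5)
#'
#' @inheritParams write_image_png
#' @export
write_image_pgm <- function(image, path, L = 256) {
  validate_image(image, L)
  if (is_color_image(image)) abort("PGM output is grayscale only.")
  if (L > 256) abort("PGM writer supports maxval up to 255.")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), L - 1)), con)
  writeBin(as.raw(as.integer(t(image))), con)
  invisible(path)
}
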