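#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities in [0, 255] with an
#' optional `dpi` attribute carrying scanner resolution metadata.  Rows are
#' image rows (y), columns are image columns (x).
#'
#' @param pixels numeric matrix with values in [0, 255], at least 2 x 2.
#' @param dpi optional positive scanner resolution in dots per inch.
#' @return a `gray_image` object.
#' @export
gray_image <- function(pixels, dpi = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    stop("intensities must be finite and within [0, 255]", call. = FALSE)
  }
  if (!is.null(dpi)) {
    stopifnot(is.numeric(dpi), length(dpi) == 1L, dpi > 0)
    attr(pixels, "dpi") <- as.numeric(dpi)
  }
  class(pixels) <- c("gray_image", class(matrix()))
  pixels
}

#' @export
print.gray_image <- function(x, ...) {
  dpi <- attr(x, "dpi")
  cat(sprintf("<gray_image> %d x %d, range [%g, %g]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(dpi)) "" else sprintf(", %g dpi", dpi)))
  invisible(x)
}

# strip the class so arithmetic on the raw matrix stays cheap
as_intensity_matrix <- function(g) {
  m <- unclass(g)
  attr(m, "dpi") <- NULL
  m
}

#' Convert a multi-channel raster to grayscale
#'
#' Three-channel input is reduced to luminance with the ITU-R BT.601 weights
#' 0.299 R + 0.587 G + 0.114 B (the convention of common imaging libraries);
#' single-channel input passes through unchanged.
#'
#' @param image either a matrix (already grayscale), an `h x w x 1` or
#'   `h x w x 3` array with values in [0, 255], or a `gray_image`.
#' @param dpi optional resolution metadata to attach.
#' @return a [gray_image()].
#' @export
to_grayscale <- function(image, dpi = NULL) {
  if (inherits(image, "gray_image")) {
    if (is.null(dpi)) return(image)
    return(gray_image(as_intensity_matrix(image), dpi = dpi))
  }
  if (is.matrix(image)) return(gray_image(image, dpi = dpi))
  if (is.array(image) && length(dim(image)) == 3L) {
    nch <- dim(image)[3]
    if (nch == 1L) return(gray_image(image[, , 1L], dpi = dpi))
    if (nch == 3L) {
      lum <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] +
             0.114 * image[, , 3L]
      return(gray_image(lum, dpi = dpi))
    }
    stop(sprintf("unsupported channel count: %d (expected 1 or 3)", nch),
         call. = FALSE)
  }
  stop("`image` must be a matrix or a 3-dimensional array", call. = FALSE)
}

#' Read a scanned root image
#'
#' Reads PNG or JPEG files (8-bit grayscale or RGB) and returns intensities
#' on the 0-255 scale.  PNG resolution metadata (pHYs chunk), when present,
#' is attached as the `dpi` attribute.  TIFF is not supported by the
#' installed readers; convert to PNG first.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return a [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  dpi <- NULL
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    info <- attr(raw, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && all(info$dpi > 0)) {
      dpi <- mean(info$dpi)
    }
  } else if (ext %in% c("jpg", "jpeg")) {
    raw <- jpeg::readJPEG(path)
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or JPEG)", ext),
         call. = FALSE)
  }
  # drop an alpha channel if present
  if (is.array(raw) && length(dim(raw)) == 3L && dim(raw)[3] %in% c(2L, 4L)) {
    raw <- raw[, , seq_len(dim(raw)[3] - 1L), drop = FALSE]
    if (dim(raw)[3] == 1L) raw <- raw[, , 1L]
  }
  to_grayscale(raw * 255, dpi = dpi)
}

#' Write a binary mask or skeleton as a PNG
#'
#' Foreground pixels are written as white (255) on black, the convention of
#' the common root-analysis viewers.
#'
#' @param mask logical matrix (mask or skeleton).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a grayscale image as a PNG
#'
#' @param g a [gray_image()] or numeric matrix on the 0-255 scale.
#' @param path output PNG path.
#' @param dpi optional resolution to embed in the PNG metadata.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(g, path, dpi = attr(g, "dpi")) {
  m <- as_intensity_matrix(g) / 255
  if (is.null(dpi)) {
    png::writePNG(m, path)
  } else {
    png::writePNG(m, path, dpi = dpi)
  }
  invisible(path)
}
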