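#' Pixel-to-centimetre calibration
#'
#' A `root_scale` records the physical size of one pixel.  It can be derived
#' from the scanner resolution ([scale_from_dpi()]) or from two points a known
#' distance apart on a scanned ruler ([scale_from_ruler()]).  All trait
#' computations take a `root_scale` and report lengths in cm, areas in cm^2
#' and volumes in cm^3.
#'
#' @param pixel_size physical size of one pixel in cm.
#' @param source how the scale was obtained, `"dpi"` or `"ruler"`.
#' @return an object of class `root_scale` with fields `pixel_size`
#'   (cm/pixel), `pixels_per_cm` (1/pixel_size) and `source`.
#' @seealso [scale_from_dpi()], [scale_from_ruler()]
#' @export
root_scale <- function(pixel_size, source = c("dpi", "ruler")) {
  source <- match.arg(source)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(pixel_size = pixel_size, pixels_per_cm = 1 / pixel_size,
         source = source),
    class = "root_scale"
  )
}

#' Calibration from scanner resolution
#'
#' Converts a scanner resolution in dots per inch to a pixel size in cm:
#' `pixels_per_cm = dpi / 2.54` and `pixel_size = 2.54 / dpi`.  At the 400 dpi
#' typically used for flatbed root scans this gives 157.48 pixels per cm, a
#' pixel size of 0.00635 cm (about 0.0063 cm).
#'
#' @param dpi scanner resolution in dots per inch; must be positive.
#' @return a [root_scale()].
#' @examples
#' scale_from_dpi(400)$pixels_per_cm  # 157.48
#' scale_from_dpi(254)$pixel_size     # exactly 0.01 cm
#' @export
scale_from_dpi <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || !is.finite(dpi) || dpi <= 0) {
    stop("`dpi` must be a single positive number", call. = FALSE)
  }
  root_scale(2.54 / dpi, source = "dpi")
}

#' Calibration from two points on a scanned ruler
#'
#' Given the pixel coordinates of two marks a known physical distance apart,
#' the pixel size is `known_length / d(p1, p2)` with `d` the Euclidean pixel
#' distance.  Euclidean distance supports rulers placed at any angle, not
#' only axis-aligned ones.
#'
#' @param p1,p2 numeric length-2 pixel coordinates `(x, y)` of the two marks.
#' @param known_length physical distance between the marks in cm.
#' @return a [root_scale()].
#' @examples
#' # 158 pixels spanning 1 cm -> pixel size 1/158 = 0.006329 cm
#' scale_from_ruler(c(0, 0), c(158, 0), 1)$pixel_size
#' @export
scale_from_ruler <- function(p1, p2, known_length) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2L || length(p2) != 2L || anyNA(p1) || anyNA(p2)) {
    stop("`p1` and `p2` must be numeric (x, y) coordinate pairs",
         call. = FALSE)
  }
  if (!is.numeric(known_length) || length(known_length) != 1L ||
      !is.finite(known_length) || known_length <= 0) {
    stop("`known_length` must be a single positive number in cm",
         call. = FALSE)
  }
  d <- sqrt(sum((p1 - p2)^2))
  if (d == 0) {
    stop("degenerate calibration: the two ruler points coincide",
         call. = FALSE)
  }
  root_scale(known_length / d, source = "ruler")
}

#' Convert between pixel counts and centimetres
#'
#' @param px,cm quantity to convert (any numeric vector).
#' @param scale a [root_scale()].
#' @return the converted numeric vector.
#' @export
px_to_cm <- function(px, scale) {
  stopifnot(inherits(scale, "root_scale"))
  px * scale$pixel_size
}

#' @rdname px_to_cm
#' @export
cm_to_px <- function(cm, scale) {
  stopifnot(inherits(scale, "root_scale"))
  cm * scale$pixels_per_cm
}

#' @export
print.root_scale <- function(x, ...) {
  cat(sprintf("<root_scale> %.6g cm/pixel (%.4f px/cm), source: %s\n",
              x$pixel_size, x$pixels_per_cm, x$source))
  invisible(x)
}
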