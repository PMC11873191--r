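#' Binary root mask
#'
#' Logical matrix where `TRUE` marks root foreground, carrying the
#' thresholding method that produced it and (for global methods) the
#' threshold value.
#'
#' @param pixels logical matrix.
#' @param provenance one of `"otsu"`, `"triangle"`, `"adaptive_mean"`,
#'   `"adaptive_gaussian"`, `"manual"`.
#' @param threshold optional global threshold value used.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(pixels,
                        provenance = c("manual", "otsu", "triangle",
                                       "adaptive_mean", "adaptive_gaussian"),
                        threshold = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.logical(pixels), is.matrix(pixels))
  attr(pixels, "provenance") <- provenance
  if (!is.null(threshold)) attr(pixels, "threshold") <- threshold
  class(pixels) <- c("binary_mask", class(matrix()))
  pixels
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground px, method: %s%s\n",
              nrow(x), ncol(x), sum(x), attr(x, "provenance"),
              if (is.null(attr(x, "threshold"))) ""
              else sprintf(" (t = %g)", attr(x, "threshold"))))
  invisible(x)
}

as_logical_matrix <- function(m) {
  out <- unclass(m)
  attributes(out) <- list(dim = dim(m))
  out
}

#' Segmentation configuration
#'
#' Bundles the preprocessing and thresholding parameters of the pipeline.
#' The defaults follow the pipeline's validated pairing: `method = "auto"`
#' uses the triangle threshold for the skeleton/length branch and Otsu for
#' the distance-transform branch.  The paper-style preprocessing chain is
#' grayscale conversion, median blur, then inversion so that roots (dark on
#' a light scan) become the bright foreground.
#'
#' @param method `"auto"` (triangle for length, Otsu for diameter traits) or
#'   one of `"otsu"`, `"triangle"`, `"adaptive_mean"`, `"adaptive_gaussian"`
#'   to force a single method for both branches.
#' @param median_kernel odd median-blur kernel size (>= 1; 1 disables).
#' @param invert logical; invert intensities so roots become bright.
#' @param block_size odd neighbourhood size for adaptive methods (>= 3).
#' @param offset_c offset subtracted from the local statistic in adaptive
#'   thresholding.
#' @param min_particle_area connected components smaller than this many
#'   pixels are removed as debris (0 disables).
#' @param connectivity 4 or 8, pixel adjacency for particle clearance.
#' @return a `seg_config` list.
#' @export
seg_config <- function(method = c("auto", "otsu", "triangle",
                                  "adaptive_mean", "adaptive_gaussian"),
                       median_kernel = 3L,
                       invert = TRUE,
                       block_size = 11L,
                       offset_c = 2,
                       min_particle_area = 50L,
                       connectivity = 8L) {
  method <- match.arg(method)
  median_kernel <- as.integer(median_kernel)
  block_size <- as.integer(block_size)
  if (median_kernel < 1L || median_kernel %% 2L == 0L) {
    stop("`median_kernel` must be an odd integer >= 1", call. = FALSE)
  }
  if (block_size < 3L || block_size %% 2L == 0L) {
    stop("`block_size` must be an odd integer >= 3", call. = FALSE)
  }
  if (min_particle_area < 0L) stop("`min_particle_area` must be >= 0",
                                   call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8",
                                         call. = FALSE)
  structure(
    list(method = method, median_kernel = median_kernel,
         invert = isTRUE(invert), block_size = block_size,
         offset_c = offset_c,
         min_particle_area = as.integer(min_particle_area),
         connectivity = as.integer(connectivity)),
    class = "seg_config"
  )
}

#' Median smoothing
#'
#' Replaces each pixel by the median of its `kernel x kernel` neighbourhood
#' (edge-replicated border); `kernel = 1` is the identity.
#'
#' @param g a [gray_image()] or numeric matrix.
#' @param kernel odd integer >= 1.
#' @return a smoothed image of the same class/shape.
#' @export
median_smooth <- function(g, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L) {
    stop("`kernel` must be an odd integer >= 1", call. = FALSE)
  }
  if (kernel == 1L) return(g)
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  out <- cpp_median_filter(m, kernel)
  gray_image(out, dpi = attr(g, "dpi"))
}

#' Intensity inversion
#'
#' Maps every intensity `v` to `255 - v`, turning dark roots on a light
#' background into bright foreground on dark background.
#'
#' @param g a [gray_image()] or numeric matrix on the 0-255 scale.
#' @return the inverted image.
#' @export
invert_image <- function(g) {
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  gray_image(255 - m, dpi = attr(g, "dpi"))
}

# 256-bin histogram of rounded intensities (bin i holds count of intensity
# i-1); thresholds are computed on this integer grid
hist256 <- function(g) {
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  v <- pmin(pmax(round(as.vector(m)), 0), 255)
  tabulate(v + 1L, nbins = 256L)
}

#' Otsu automatic threshold
#'
#' Chooses the threshold `t` in 0..255 maximising the between-class variance
#' of the 256-bin intensity histogram (equivalently minimising the pooled
#' within-class variance).  Ties are broken toward the smallest `t`.  The
#' input is expected in root-bright polarity (after [invert_image()]); the
#' returned mask marks pixels with intensity strictly greater than `t` as
#' foreground.
#'
#' @param g a [gray_image()] or numeric matrix (root-bright polarity).
#' @return a list with `mask` (a [binary_mask()]) and `threshold` (integer).
#' @export
threshold_otsu <- function(g) {
  counts <- hist256(g)
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  t <- otsu_from_hist(counts)
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  list(mask = binary_mask(m > t, provenance = "otsu", threshold = t),
       threshold = t)
}

# between-class variance maximisation on a 256-bin histogram; returns the
# smallest maximiser.  Class 0 is intensities <= t, class 1 is > t.
otsu_from_hist <- function(counts) {
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)              # weight of class 0 at threshold t = 0..255
  mu <- cumsum(p * levels)        # first moment of class 0
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  # t = 255 leaves class 1 empty and is never a valid split
  sigma_b[256L] <- -Inf
  which.max(sigma_b) - 1L
}

#' Triangle automatic threshold
#'
#' Draws a line from the histogram peak to the far end of the longer tail
#' (the farthest non-empty bin, taken at height zero) and thresholds at the
#' bin maximising the signed perpendicular distance below that line.  Suited to strongly
#' skewed histograms where a large background peak dominates, which is the
#' typical root-scan situation.  Ties break toward the bin nearest the tail.
#' Polarity convention as in [threshold_otsu()].
#'
#' @inheritParams threshold_otsu
#' @return a list with `mask` and `threshold`.
#' @export
threshold_triangle <- function(g) {
  counts <- hist256(g)
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  t <- triangle_from_hist(counts)
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  list(mask = binary_mask(m > t, provenance = "triangle", threshold = t),
       threshold = t)
}

# geometric triangle threshold on a 256-bin histogram (bins 0..255).
# Baseline runs from the peak (peak, h_peak) to the farther histogram
# extreme (tail_end, 0); the distance is SIGNED, positive for bins lying
# below the chord, so a tall bin at the tail end can never win.  Ties break
# toward the tail end.
triangle_from_hist <- function(counts) {
  nz <- which(counts > 0L)
  first <- nz[1L] - 1L
  last <- nz[length(nz)] - 1L
  peak <- which.max(counts) - 1L
  tail_end <- if ((peak - first) >= (last - peak)) first else last
  lo <- min(peak, tail_end); hi <- max(peak, tail_end)
  if (lo == hi) return(lo)
  xs <- lo:hi
  h_peak <- counts[peak + 1L]
  base <- abs(peak - tail_end)
  s <- h_peak * abs(xs - tail_end) - base * counts[xs + 1L]
  ord <- order(abs(xs - tail_end))   # nearest-tail-first scan; first argmax
  best <- ord[which.max(s[ord])]
  xs[best]
}

#' Adaptive (local) thresholding
#'
#' Classifies a pixel as foreground when it is brighter than its local
#' neighbourhood statistic by more than `offset_c`: with the root-bright
#' polarity used throughout the pipeline, `foreground = v - local > C` where
#' `local` is the `block_size x block_size` neighbourhood mean (mode
#' `"mean"`) or Gaussian-weighted mean (mode `"gaussian"`).  On a constant
#' image with `offset_c > 0` the foreground is empty.
#'
#' @inheritParams threshold_otsu
#' @param mode `"mean"` or `"gaussian"`.
#' @param block_size odd neighbourhood size >= 3.
#' @param offset_c offset subtracted from the local statistic.
#' @param sigma Gaussian sigma; the default (<= 0) uses the conventional
#'   kernel-size rule `0.3 * ((block_size - 1) / 2 - 1) + 0.8`.
#' @return a [binary_mask()].
#' @export
threshold_adaptive <- function(g, mode = c("mean", "gaussian"),
                               block_size = 11L, offset_c = 2, sigma = -1) {
  mode <- match.arg(mode)
  block_size <- as.integer(block_size)
  if (block_size < 3L || block_size %% 2L == 0L) {
    stop("`block_size` must be an odd integer >= 3", call. = FALSE)
  }
  m <- if (inherits(g, "gray_image")) as_intensity_matrix(g) else g
  local <- cpp_local_mean(m, block_size, mode == "gaussian", sigma)
  binary_mask(m - local > offset_c,
              provenance = if (mode == "mean") "adaptive_mean"
                           else "adaptive_gaussian")
}

#' Particle clearance: drop small connected components
#'
#' Removes every foreground component with fewer than `min_area` pixels,
#' suppressing scanner debris and salt noise.  `min_area = 0` is the
#' identity; the operation is idempotent and never adds foreground.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param min_area minimum component size (pixels) to keep.
#' @param connectivity 4 or 8.
#' @return the filtered mask (provenance preserved).
#' @export
remove_small_components <- function(mask, min_area = 50L, connectivity = 8L) {
  stopifnot(min_area >= 0, connectivity %in% c(4L, 8L))
  if (min_area == 0L) return(mask)
  m <- as_logical_matrix(mask)
  lab <- cpp_label(m, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- sizes >= min_area
  out <- m & keep[ifelse(lab > 0L, lab, NA_integer_)]
  out[is.na(out)] <- FALSE
  dim(out) <- dim(m)
  binary_mask(out,
              provenance = attr(mask, "provenance") %||% "manual",
              threshold = attr(mask, "threshold"))
}

#' Count foreground connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer component count.
#' @export
count_components <- function(mask, connectivity = 8L) {
  max(cpp_label(as_logical_matrix(mask), as.integer(connectivity)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared preprocessing chain: grayscale input -> median blur -> inversion
preprocess_image <- function(g, config) {
  g <- to_grayscale(g, dpi = attr(g, "dpi"))
  g <- median_smooth(g, config$median_kernel)
  if (config$invert) g <- invert_image(g)
  g
}

# run one thresholding method on a preprocessed (root-bright) image
segment_with <- function(g, method, config) {
  res <- switch(method,
    otsu = threshold_otsu(g),
    triangle = threshold_triangle(g),
    adaptive_mean = list(
      mask = threshold_adaptive(g, "mean", config$block_size,
                                config$offset_c),
      threshold = NA_real_),
    adaptive_gaussian = list(
      mask = threshold_adaptive(g, "gaussian", config$block_size,
                                config$offset_c),
      threshold = NA_real_),
    stop("unknown method: ", method, call. = FALSE)
  )
  res$mask <- remove_small_components(res$mask, config$min_particle_area,
                                      config$connectivity)
  res
}
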