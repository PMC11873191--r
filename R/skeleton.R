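#' Morphological thinning to a one-pixel skeleton
#'
#' Iteratively peels boundary pixels off the binary mask until no pixel can
#' be removed without breaking connectivity, using the Zhang-Suen
#' two-subiteration parallel thinning rules.  The mask is padded with a
#' one-pixel background ring during iteration (and cropped afterwards) so
#' roots touching the image border thin cleanly.  A topology-safe clean-up
#' pass then removes any residual 2 x 2 foreground square, so the result is
#' strictly one pixel wide.
#'
#' Properties: the skeleton is a subset of the mask, thinning is idempotent,
#' and the foreground component count is preserved for structures wider than
#' a single 2 x 2 block (an isolated 2 x 2 blob is degenerate for the
#' parallel rules and is normally removed beforehand by particle clearance).
#' No pruning is applied, so short lateral spurs survive.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return a logical matrix of class `skeleton` (attribute
#'   `source_mask_shape` records the mask dimensions).
#' @export
thin <- function(mask) {
  m <- as_logical_matrix(mask)
  if (!any(m)) {
    message("thin(): empty mask, returning empty skeleton")
    out <- m
  } else {
    out <- cpp_thin_zs(m)
  }
  attr(out, "source_mask_shape") <- dim(m)
  class(out) <- c("skeleton", class(matrix()))
  out
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %d x %d, %d pixels\n", nrow(x), ncol(x), sum(x)))
  invisible(x)
}
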