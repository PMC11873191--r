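#' Euclidean distance transform
#'
#' Assigns each foreground pixel its exact Euclidean distance (in pixel
#' units, between pixel centres) to the nearest background pixel; background
#' pixels get 0.  An exact transform is used (not a chamfer approximation)
#' because the distance at a skeleton pixel is interpreted directly as the
#' local root radius.  An all-foreground mask has no interior background, so
#' a one-pixel background ring is assumed at the image boundary in that case
#' (logged).
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @return a numeric matrix of class `distance_map`.
#' @export
distance_transform <- function(mask) {
  m <- as_logical_matrix(mask)
  if (all(m)) {
    message("distance_transform(): all-foreground mask, ",
            "assuming background ring at the image boundary")
    nr <- nrow(m); nc <- ncol(m)
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- TRUE
    d <- sqrt(cpp_edt_sq(pad))[2:(nr + 1L), 2:(nc + 1L)]
  } else {
    d <- sqrt(cpp_edt_sq(m))
  }
  class(d) <- c("distance_map", class(matrix()))
  d
}

# pad a logical matrix with a FALSE ring (simplifies neighbour shifts)
pad_false <- function(m) {
  out <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

#' Total root length from a skeleton
#'
#' Sums step lengths over unique pairs of 8-adjacent skeleton pixels:
#' orthogonal steps count 1 pixel, diagonal steps count sqrt(2) = 1.4142
#' pixels (the Euclidean distance between diagonally adjacent pixel
#' centres).  A diagonal pair is skipped when its two pixels share an
#' orthogonal skeleton neighbour completing a triangle, which prevents
#' double counting at corners.  The total is multiplied by the pixel size.
#'
#' With `rule = "pixels"` a literal per-pixel count is used instead: each
#' skeleton pixel contributes sqrt(2) when it connects to the chain only
#' diagonally, and 1 otherwise.  This variant is provided for comparability
#' and is not the default.
#'
#' @param skeleton a [thin()] result or logical matrix.
#' @param scale a [root_scale()].
#' @param rule `"edges"` (default) or `"pixels"`.
#' @return total root length in cm (0 for an empty skeleton).
#' @export
total_root_length <- function(skeleton, scale, rule = c("edges", "pixels")) {
  rule <- match.arg(rule)
  stopifnot(inherits(scale, "root_scale"))
  s <- pad_false(as_logical_matrix(skeleton))
  if (!any(s)) return(0)
  nr <- nrow(s); nc <- ncol(s)

  # unique adjacent pairs via half-neighbourhood shifts
  right  <- s[, -nc] & s[, -1]                    # (r,c)   - (r,c+1)
  down   <- s[-nr, ] & s[-1, ]                    # (r,c)   - (r+1,c)
  dr     <- s[-nr, -nc] & s[-1, -1]               # (r,c)   - (r+1,c+1)
  dl     <- s[-nr, -1] & s[-1, -nc]               # (r,c+1) - (r+1,c)
  # triangle suppression: drop a diagonal whose corner is already linked
  # through an orthogonal neighbour shared by both endpoints
  dr_keep <- dr & !(s[-nr, -1] | s[-1, -nc])
  dl_keep <- dl & !(s[-nr, -nc] | s[-1, -1])

  if (rule == "edges") {
    n_orth <- sum(right) + sum(down)
    n_diag <- sum(dr_keep) + sum(dl_keep)
    return(scale$pixel_size * (n_orth + sqrt(2) * n_diag))
  }

  # literal per-pixel reading: a pixel joined to the chain only through
  # (unsuppressed) diagonal contacts is weighted sqrt(2)
  has_orth <- matrix(FALSE, nr, nc)
  has_orth[, -nc] <- has_orth[, -nc] | right
  has_orth[, -1]  <- has_orth[, -1]  | right
  has_orth[-nr, ] <- has_orth[-nr, ] | down
  has_orth[-1, ]  <- has_orth[-1, ]  | down
  has_diag <- matrix(FALSE, nr, nc)
  has_diag[-nr, -nc] <- has_diag[-nr, -nc] | dr_keep
  has_diag[-1, -1]   <- has_diag[-1, -1]   | dr_keep
  has_diag[-nr, -1]  <- has_diag[-nr, -1]  | dl_keep
  has_diag[-1, -nc]  <- has_diag[-1, -nc]  | dl_keep
  w <- ifelse(s & has_diag & !has_orth, sqrt(2), as.numeric(s))
  scale$pixel_size * sum(w)
}

#' Radii sampled along the skeleton
#'
#' For each skeleton pixel the distance-transform value is read off and
#' converted to a physical radius, `r = DT * pixel_size`.  At a medial
#' (skeleton) pixel the distance to the nearest background approximates the
#' local half-width of the root.  Radii are returned in deterministic
#' row-major order.
#'
#' @param skeleton logical skeleton matrix (must lie inside the mask that
#'   produced `dmap`).
#' @param dmap a [distance_transform()] result of the same shape.
#' @param scale a [root_scale()].
#' @return numeric vector of radii in cm (empty for an empty skeleton).
#' @export
radii_along_skeleton <- function(skeleton, dmap, scale) {
  stopifnot(inherits(scale, "root_scale"))
  s <- as_logical_matrix(skeleton)
  if (!identical(dim(s), dim(dmap))) {
    stop("skeleton and distance map have different shapes", call. = FALSE)
  }
  idx <- which(s, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(numeric(0))
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dt <- unclass(dmap)[idx]
  if (any(dt <= 0)) {
    stop("internal consistency error: skeleton pixel outside the mask ",
         "(distance transform is zero there)", call. = FALSE)
  }
  dt * scale$pixel_size
}

#' Average root diameter
#'
#' Mean diameter over all skeleton pixels: each radius is doubled, summed,
#' and divided by the number of skeleton pixels, `AD = sum(2 r_i) / N`.
#'
#' @param radii radii in cm from [radii_along_skeleton()].
#' @return average diameter in cm.
#' @export
average_diameter <- function(radii) {
  if (length(radii) == 0L) {
    stop("undefined trait: average diameter of an empty skeleton",
         call. = FALSE)
  }
  sum(2 * radii) / length(radii)
}

#' Root surface area
#'
#' Models the root locally as a cylinder: each skeleton pixel contributes
#' its circumference `2 pi r_i`, and the summed circumference times the
#' pixel size (the length each pixel represents) gives the lateral surface,
#' `SA = ps * sum(2 pi r_i)`.
#'
#' @inheritParams average_diameter
#' @param scale a [root_scale()].
#' @return surface area in cm^2 (0 for empty input, logged).
#' @export
surface_area <- function(radii, scale) {
  stopifnot(inherits(scale, "root_scale"))
  if (length(radii) == 0L) {
    message("surface_area(): empty radius list, returning 0")
    return(0)
  }
  scale$pixel_size * sum(2 * pi * radii)
}

#' Root volume
#'
#' Per-pixel circular cross-sections `pi r_i^2` summed along the skeleton
#' and multiplied by the pixel size: `RV = ps * sum(pi r_i^2)`.
#'
#' @inheritParams surface_area
#' @return volume in cm^3 (0 for empty input, logged).
#' @export
root_volume <- function(radii, scale) {
  stopifnot(inherits(scale, "root_scale"))
  if (length(radii) == 0L) {
    message("root_volume(): empty radius list, returning 0")
    return(0)
  }
  scale$pixel_size * sum(pi * radii^2)
}

#' Projected root area
#'
#' Silhouette area of the segmented root: foreground pixel count times the
#' pixel area, `PA = N_fg * ps^2`.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param scale a [root_scale()].
#' @return projected area in cm^2.
#' @export
projected_area <- function(mask, scale) {
  stopifnot(inherits(scale, "root_scale"))
  sum(as_logical_matrix(mask)) * scale$pixel_size^2
}

#' Estimated traits from projected area (cylinder model)
#'
#' The trigonometric estimates used by commercial root scanners treat the
#' whole root system as one cylinder seen in projection: `SA_est = PA * pi`,
#' `AD_est = PA / TRL`, and `RV_est = pi * (AD_est / 2)^2 * TRL`.
#'
#' @param pa projected area in cm^2.
#' @param trl total root length in cm; must be positive.
#' @return list with `sa_est` (cm^2), `ad_est` (cm), `rv_est` (cm^3).
#' @export
estimated_traits <- function(pa, trl) {
  if (!is.numeric(trl) || length(trl) != 1L || !is.finite(trl) || trl <= 0) {
    stop("undefined trait: estimated traits require TRL > 0", call. = FALSE)
  }
  if (!is.numeric(pa) || length(pa) != 1L || !is.finite(pa) || pa < 0) {
    stop("`pa` must be a single non-negative number", call. = FALSE)
  }
  ad_est <- pa / trl
  list(sa_est = pa * pi,
       ad_est = ad_est,
       rv_est = pi * (ad_est / 2)^2 * trl)
}

# rethrow any stage error with the pipeline stage named
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Full trait record for one root image
#'
#' Runs the complete measurement chain on one grayscale scan.  With the
#' default `method = "auto"` two segmentation branches are used, following
#' the validated pairing: the triangle threshold drives the skeleton/length
#' branch (it preserves thin laterals through thinning), while the Otsu
#' threshold drives the distance-transform branch (its mask widths match
#' reference software diameters) and supplies the projected area.  Forcing
#' `config$method` runs both branches from the single requested method.
#'
#' Stages: grayscale conversion, median blur, inversion (roots become
#' bright), thresholding, particle clearance, thinning, distance transform,
#' trait aggregation, and the projected-area-based estimated traits.
#'
#' @param image a [gray_image()], matrix, or `h x w x 3` array on the 0-255
#'   scale (dark roots on light background).
#' @param config a [seg_config()].
#' @param scale a [root_scale()]; defaults to the image's `dpi` attribute
#'   when present.
#' @param length_rule passed to [total_root_length()].
#' @return an object of class `root_traits`: a list with fields `trl`, `ad`,
#'   `sa`, `rv`, `projected_area` (cm-based units), the estimated variants
#'   `sa_est`, `ad_est`, `rv_est`, `n_skeleton_pixels` (length branch),
#'   `n_radius_pixels` (distance-transform branch), the thresholds used, the
#'   `scale`, and the method pairing.
#' @export
analyze_root <- function(image, config = seg_config(), scale = NULL,
                         length_rule = c("edges", "pixels")) {
  length_rule <- match.arg(length_rule)
  stopifnot(inherits(config, "seg_config"))
  if (is.null(scale)) {
    dpi <- attr(image, "dpi")
    if (is.null(dpi)) {
      stop("no `scale` supplied and the image carries no dpi metadata",
           call. = FALSE)
    }
    scale <- scale_from_dpi(dpi)
  }
  stopifnot(inherits(scale, "root_scale"))

  g <- with_stage("preprocess", preprocess_image(image, config))

  # a blank (constant) scan has a degenerate histogram: report zero traits
  if (sum(hist256(g) > 0L) < 2L) {
    warning("blank scan: constant image, all traits are 0", call. = FALSE)
    return(new_root_traits(
      trl = 0, ad = 0, sa = 0, rv = 0, projected_area = 0,
      sa_est = 0, ad_est = 0, rv_est = 0,
      n_skeleton_pixels = 0L, n_radius_pixels = 0L,
      threshold_trl = NA_real_, threshold_dt = NA_real_,
      method_trl = if (config$method == "auto") "triangle" else config$method,
      method_dt = if (config$method == "auto") "otsu" else config$method,
      scale = scale))
  }

  methods <- if (config$method == "auto") {
    c(trl = "triangle", dt = "otsu")
  } else {
    c(trl = config$method, dt = config$method)
  }

  seg_trl <- with_stage("segmentation", segment_with(g, methods[["trl"]],
                                                     config))
  seg_dt <- if (methods[["trl"]] == methods[["dt"]]) seg_trl else
    with_stage("segmentation", segment_with(g, methods[["dt"]], config))

  if (!any(seg_trl$mask) && !any(seg_dt$mask)) {
    warning("blank scan: no foreground after segmentation; all traits are 0",
            call. = FALSE)
    return(new_root_traits(
      trl = 0, ad = 0, sa = 0, rv = 0, projected_area = 0,
      sa_est = 0, ad_est = 0, rv_est = 0,
      n_skeleton_pixels = 0L, n_radius_pixels = 0L,
      threshold_trl = seg_trl$threshold, threshold_dt = seg_dt$threshold,
      method_trl = methods[["trl"]], method_dt = methods[["dt"]],
      scale = scale))
  }

  # length branch
  skel_trl <- with_stage("thinning", suppressMessages(thin(seg_trl$mask)))
  trl <- with_stage("length", total_root_length(skel_trl, scale,
                                                rule = length_rule))

  # distance-transform branch
  dmap <- with_stage("distance transform",
                     suppressMessages(distance_transform(seg_dt$mask)))
  skel_dt <- with_stage("thinning", suppressMessages(thin(seg_dt$mask)))
  radii <- with_stage("radii", radii_along_skeleton(skel_dt, dmap, scale))
  ad <- if (length(radii)) average_diameter(radii) else 0
  sa <- suppressMessages(surface_area(radii, scale))
  rv <- suppressMessages(root_volume(radii, scale))
  pa <- projected_area(seg_dt$mask, scale)

  if (trl > 0) {
    est <- with_stage("estimated traits", estimated_traits(pa, trl))
  } else {
    warning("TRL is 0; estimated traits set to 0", call. = FALSE)
    est <- list(sa_est = 0, ad_est = 0, rv_est = 0)
  }

  new_root_traits(
    trl = trl, ad = ad, sa = sa, rv = rv, projected_area = pa,
    sa_est = est$sa_est, ad_est = est$ad_est, rv_est = est$rv_est,
    n_skeleton_pixels = sum(skel_trl), n_radius_pixels = length(radii),
    threshold_trl = seg_trl$threshold, threshold_dt = seg_dt$threshold,
    method_trl = methods[["trl"]], method_dt = methods[["dt"]],
    scale = scale)
}

new_root_traits <- function(trl, ad, sa, rv, projected_area, sa_est, ad_est,
                            rv_est, n_skeleton_pixels, n_radius_pixels,
                            threshold_trl, threshold_dt, method_trl,
                            method_dt, scale) {
  vals <- c(trl = trl, ad = ad, sa = sa, rv = rv, pa = projected_area,
            sa_est = sa_est, ad_est = ad_est, rv_est = rv_est)
  stopifnot(all(vals >= 0), n_skeleton_pixels >= 0L)
  structure(
    list(trl = trl, ad = ad, sa = sa, rv = rv,
         projected_area = projected_area,
         sa_est = sa_est, ad_est = ad_est, rv_est = rv_est,
         n_skeleton_pixels = as.integer(n_skeleton_pixels),
         n_radius_pixels = as.integer(n_radius_pixels),
         threshold_trl = threshold_trl, threshold_dt = threshold_dt,
         method_trl = method_trl, method_dt = method_dt,
         scale = scale),
    class = "root_traits")
}

#' @export
print.root_traits <- function(x, ...) {
  cat("<root_traits>\n")
  cat(sprintf("  TRL  %10.4f cm    (skeleton: %d px, method %s)\n",
              x$trl, x$n_skeleton_pixels, x$method_trl))
  cat(sprintf("  AD   %10.4f cm    (method %s)\n", x$ad, x$method_dt))
  cat(sprintf("  SA   %10.4f cm^2\n", x$sa))
  cat(sprintf("  RV   %10.4f cm^3\n", x$rv))
  cat(sprintf("  PA   %10.4f cm^2\n", x$projected_area))
  cat(sprintf("  est. SA %7.4f cm^2, AD %.4f cm, RV %.6f cm^3\n",
              x$sa_est, x$ad_est, x$rv_est))
  cat(sprintf("  pixel size %.6g cm\n", x$scale$pixel_size))
  invisible(x)
}

#' Flatten a trait record to a one-row data frame
#'
#' @param x a `root_traits` object.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (ignored).
#' @return a one-row data frame.
#' @export
as.data.frame.root_traits <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    pixel_size = x$scale$pixel_size,
    TRL_cm = x$trl, AD_cm = x$ad, SA_cm2 = x$sa, RV_cm3 = x$rv,
    PA_cm2 = x$projected_area,
    SA_est_cm2 = x$sa_est, AD_est_cm = x$ad_est, RV_est_cm3 = x$rv_est,
    n_skeleton_pixels = x$n_skeleton_pixels,
    threshold_trl = if (is.null(x$threshold_trl)) NA_real_
                    else as.numeric(x$threshold_trl),
    threshold_dt = if (is.null(x$threshold_dt)) NA_real_
                   else as.numeric(x$threshold_dt),
    method_trl = x$method_trl, method_dt = x$method_dt,
    stringsAsFactors = FALSE)
}
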