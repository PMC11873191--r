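#' Wire specification for phantom images
#'
#' Describes one synthetic "wire": a polyline stroked with a constant odd
#' width, mimicking the physical wires of known length and diameter that are
#' scanned to validate root-measurement software.
#'
#' @param path numeric n x 2 matrix of `(x, y)` pixel coordinates (n >= 2);
#'   x runs along columns, y along rows.
#' @param width_px odd positive stroke width in pixels.
#' @param intensity dark gray level of the wire, in [0, 80].
#' @return a `wire_spec` object.
#' @export
wire_spec <- function(path, width_px, intensity = 30) {
  path <- as.matrix(path)
  if (nrow(path) < 2L || ncol(path) != 2L || anyNA(path)) {
    stop("`path` must be an n x 2 coordinate matrix with n >= 2",
         call. = FALSE)
  }
  width_px <- as.integer(width_px)
  if (width_px < 1L || width_px %% 2L == 0L) {
    stop("`width_px` must be an odd positive integer", call. = FALSE)
  }
  if (intensity < 0 || intensity > 80) {
    stop("`intensity` must lie in [0, 80] (wires are dark)", call. = FALSE)
  }
  structure(list(path = path, width_px = width_px, intensity = intensity),
            class = "wire_spec")
}

# polyline length in pixels (Euclidean, through the given vertices)
polyline_length_px <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

# disc-swept stroke rasterisation: pixel centre (c, r) is inside the stroke
# iff its distance to the polyline is <= width/2.  No anti-aliasing, so
# thresholding is exercised by noise rather than by soft edges.
stroke_mask <- function(wire, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  half <- wire$width_px / 2
  path <- wire$path
  for (k in seq_len(nrow(path) - 1L)) {
    p <- path[k, ]; q <- path[k + 1L, ]
    r_lo <- max(1L, floor(min(p[2], q[2]) - half - 1))
    r_hi <- min(nr, ceiling(max(p[2], q[2]) + half + 1))
    c_lo <- max(1L, floor(min(p[1], q[1]) - half - 1))
    c_hi <- min(nc, ceiling(max(p[1], q[1]) + half + 1))
    if (r_lo > r_hi || c_lo > c_hi) next
    rs <- r_lo:r_hi; cs <- c_lo:c_hi
    X <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    Y <- matrix(rs, length(rs), length(cs))
    v <- q - p
    len2 <- sum(v^2)
    if (len2 == 0) {
      d2 <- (X - p[1])^2 + (Y - p[2])^2
    } else {
      t <- pmin(pmax(((X - p[1]) * v[1] + (Y - p[2]) * v[2]) / len2, 0), 1)
      d2 <- (X - (p[1] + t * v[1]))^2 + (Y - (p[2] + t * v[2]))^2
    }
    mask[rs, cs] <- mask[rs, cs] | (d2 <= half^2)
  }
  mask
}

#' Closed-form ground truth for a wire
#'
#' Treats the wire as a straight circular cylinder: surface `pi * d * L`,
#' volume `pi * (d/2)^2 * L`, projected (silhouette) area `d * L`.
#'
#' @param length_cm,diameter_cm wire dimensions in cm.
#' @return a `phantom_truth` list with `length_cm`, `diameter_cm`,
#'   `sa_cm2`, `volume_cm3`, `pa_cm2`.
#' @export
phantom_truth <- function(length_cm, diameter_cm) {
  stopifnot(length_cm > 0, diameter_cm > 0)
  structure(list(length_cm = length_cm,
                 diameter_cm = diameter_cm,
                 sa_cm2 = pi * diameter_cm * length_cm,
                 volume_cm3 = pi * (diameter_cm / 2)^2 * length_cm,
                 pa_cm2 = diameter_cm * length_cm),
            class = "phantom_truth")
}

#' Render a ground-truth wire phantom
#'
#' Draws dark wires on a light canvas (background 235) at a stated DPI and
#' adds seeded Gaussian pixel noise, emulating a scanned validation tray.
#' Each wire's expected traits are computed in closed form from its polyline
#' length and stroke width via the DPI scale.
#'
#' @param wires list of [wire_spec()] objects.
#' @param canvas `c(height, width)` of the canvas in pixels.
#' @param dpi resolution used both for the scale and the image metadata.
#' @param noise_sd standard deviation of additive Gaussian noise (gray
#'   levels); 0 disables noise.
#' @param seed integer RNG seed for the noise (the caller's RNG state is
#'   restored afterwards).
#' @param background background gray level.
#' @return a list with `image` (a [gray_image()]) and `truth` (a list of
#'   [phantom_truth()], one per wire, in input order).
#' @export
render_phantom <- function(wires, canvas = c(200, 200), dpi = 400,
                           noise_sd = 0, seed = 1L, background = 235) {
  stopifnot(noise_sd >= 0, dpi > 0, length(canvas) == 2L)
  nr <- as.integer(canvas[1]); nc <- as.integer(canvas[2])
  ps <- 2.54 / dpi
  img <- matrix(background, nr, nc)
  truths <- vector("list", length(wires))
  masks <- vector("list", length(wires))

  for (i in seq_along(wires)) {
    w <- wires[[i]]
    if (!inherits(w, "wire_spec")) stop("`wires` must be wire_spec objects",
                                        call. = FALSE)
    m <- stroke_mask(w, nr, nc)
    if (!any(m)) stop("invalid fixture: wire ", i, " misses the canvas",
                      call. = FALSE)
    if (any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc])) {
      stop("invalid fixture: wire ", i, " touches the canvas edge",
           call. = FALSE)
    }
    for (j in seq_len(i - 1L)) {
      if (any(m & masks[[j]])) {
        stop(sprintf("invalid fixture: wires %d and %d overlap", j, i),
             call. = FALSE)
      }
    }
    masks[[i]] <- m
    img[m] <- w$intensity
    truths[[i]] <- phantom_truth(length_cm = polyline_length_px(w$path) * ps,
                                 diameter_cm = w$width_px * ps)
  }

  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    img <- pmin(pmax(round(img), 0), 255)
  }

  list(image = gray_image(img, dpi = dpi), truth = truths)
}

#' Render a synthetic scanned ruler
#'
#' Draws tick marks at exact centimetre intervals (`dpi / 2.54` pixels
#' apart, positions rounded to the pixel grid, so consecutive spacings at
#' 400 dpi alternate between 157 and 158 px) over a light background, for
#' exercising [scale_from_ruler()].
#'
#' @param dpi resolution in dots per inch.
#' @param length_cm integer ruler length in cm.
#' @return a [gray_image()] with tick x-positions in attribute `ticks_px`.
#' @export
render_ruler <- function(dpi, length_cm = 5L) {
  stopifnot(dpi > 0, length_cm >= 1)
  ppc <- dpi / 2.54
  margin <- 20L
  ticks <- margin + round((0:length_cm) * ppc)
  nc <- max(ticks) + margin
  nr <- 60L
  img <- matrix(235, nr, nc)
  img[10:50, ticks] <- 30          # tick marks
  img[48:50, margin:(nc - margin)] <- 30   # baseline
  g <- gray_image(img, dpi = dpi)
  attr(g, "ticks_px") <- ticks
  g
}

#' Default phantom grid
#'
#' The validation grid spans fine to coarse roots: stroke widths 3, 5, 9
#' and 15 px crossed with lengths 100, 300 and 600 px.  Each combination is
#' rendered as a single horizontal wire on its own canvas.
#'
#' @param widths_px odd stroke widths in pixels.
#' @param lengths_px wire lengths in pixels.
#' @return a data frame with columns `width_px` and `length_px`.
#' @export
default_wire_grid <- function(widths_px = c(3, 5, 9, 15),
                              lengths_px = c(100, 300, 600)) {
  expand.grid(width_px = widths_px, length_px = lengths_px,
              KEEP.OUT.ATTRS = FALSE)
}

# single horizontal wire centred on its own canvas
single_wire_phantom <- function(width_px, length_px, dpi = 400,
                                noise_sd = 0, seed = 1L) {
  margin <- ceiling(width_px / 2) + 12L
  nr <- as.integer(width_px + 2L * margin)
  nc <- as.integer(length_px + 2L * margin)
  y <- (nr + 1) / 2
  w <- wire_spec(rbind(c(margin + 1, y), c(margin + 1 + length_px, y)),
                 width_px = width_px)
  render_phantom(list(w), canvas = c(nr, nc), dpi = dpi,
                 noise_sd = noise_sd, seed = seed)
}

#' Write a directory of phantom fixtures with ground truth
#'
#' Renders the phantom grid as PNG images plus a `truth.csv` whose columns
#' (`filename`, `TRL_cm`, `AD_cm`, `SA_cm2`, `RV_cm3`, `PA_cm2`) can be fed
#' to [compare_traits()] as the reference table.
#'
#' @param out_dir output directory (created if missing).
#' @param dpi resolution of the phantoms.
#' @param seed noise seed; fixture `i` uses `seed + i` so images differ.
#' @param noise_sd Gaussian noise level in gray levels.
#' @param grid a data frame as from [default_wire_grid()].
#' @return the truth data frame, invisibly.
#' @export
make_fixtures <- function(out_dir, dpi = 400, seed = 42L, noise_sd = 5,
                          grid = default_wire_grid()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    w <- grid$width_px[i]; l <- grid$length_px[i]
    ph <- single_wire_phantom(w, l, dpi = dpi, noise_sd = noise_sd,
                              seed = seed + i)
    fn <- sprintf("phantom_w%02d_l%04d.png", w, l)
    write_gray_png(ph$image, file.path(out_dir, fn), dpi = dpi)
    tr <- ph$truth[[1]]
    rows[[i]] <- data.frame(filename = fn, width_px = w, length_px = l,
                            TRL_cm = tr$length_cm, AD_cm = tr$diameter_cm,
                            SA_cm2 = tr$sa_cm2, RV_cm3 = tr$volume_cm3,
                            PA_cm2 = tr$pa_cm2, seed = seed + i,
                            noise_sd = noise_sd,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}
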