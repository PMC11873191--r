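#' Batch analysis of a directory of root scans
#'
#' Runs [analyze_root()] over every readable PNG/JPEG in `input`, collects
#' one row per image, and (optionally) writes a CSV report plus a sidecar
#' JSON with full-precision values and the effective configuration.
#' Per-image failures are logged as warnings and skipped; they are not
#' fatal.  The pipeline is deterministic: identical inputs and
#' configuration produce identical outputs.
#'
#' Scale resolution, in order of precedence: an explicit `scale`, then
#' `pixel_size`, then `dpi`, then per-image resolution metadata.  When an
#' explicit scale overrides image metadata a notice is emitted.
#'
#' @param input directory containing images, or a character vector of image
#'   paths.
#' @param out_csv optional output CSV path.  Numeric columns are written
#'   with 6 significant digits; the sidecar `<out_csv>.json` keeps full
#'   precision.
#' @param scale optional [root_scale()].
#' @param dpi,pixel_size alternative scale sources.
#' @param config a [seg_config()].
#' @param length_rule passed to [analyze_root()].
#' @param reference optional reference CSV path (columns `filename` and
#'   trait columns) for an agreement report via [compare_traits()].
#' @param save_intermediates optional directory; when set, the binary masks
#'   and skeletons of each image are written there as PNGs.
#' @return a list with `traits` (data frame, one row per analysed image),
#'   `report` (agreement data frame or `NULL`), `skipped` (character vector
#'   of failed files).
#' @export
run_batch <- function(input, out_csv = NULL, scale = NULL, dpi = NULL,
                      pixel_size = NULL, config = seg_config(),
                      length_rule = "edges", reference = NULL,
                      save_intermediates = NULL) {
  files <- if (length(input) == 1L && dir.exists(input)) {
    list.files(input, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
               full.names = TRUE)
  } else {
    input
  }
  if (length(files) == 0L) {
    stop("empty input: no readable images found", call. = FALSE)
  }

  explicit_scale <- scale
  if (is.null(explicit_scale) && !is.null(pixel_size)) {
    explicit_scale <- root_scale(pixel_size, source = "ruler")
  }
  if (is.null(explicit_scale) && !is.null(dpi)) {
    explicit_scale <- scale_from_dpi(dpi)
  }

  if (!is.null(save_intermediates)) {
    dir.create(save_intermediates, showWarnings = FALSE, recursive = TRUE)
  }

  rows <- list()
  skipped <- character(0)
  for (f in files) {
    res <- tryCatch({
      img <- read_gray_image(f)
      sc <- explicit_scale
      if (!is.null(sc) && !is.null(attr(img, "dpi"))) {
        message("using explicit scale for ", basename(f),
                " (image dpi metadata ignored)")
      }
      tr <- suppressMessages(
        analyze_root(img, config = config, scale = sc,
                     length_rule = length_rule))
      if (!is.null(save_intermediates)) {
        stem <- tools::file_path_sans_ext(basename(f))
        g <- preprocess_image(img, config)
        methods <- if (config$method == "auto") c("triangle", "otsu")
                   else config$method
        for (m in unique(methods)) {
          sm <- suppressMessages(segment_with(g, m, config))
          write_mask_png(as_logical_matrix(sm$mask),
                         file.path(save_intermediates,
                                   sprintf("%s_mask_%s.png", stem, m)))
          write_mask_png(as_logical_matrix(suppressMessages(thin(sm$mask))),
                         file.path(save_intermediates,
                                   sprintf("%s_skeleton_%s.png", stem, m)))
        }
      }
      cbind(data.frame(filename = basename(f), stringsAsFactors = FALSE),
            as.data.frame(tr))
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, basename(f)) else
      rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    stop("empty input: no image could be analysed", call. = FALSE)
  }
  traits <- do.call(rbind, rows)
  rownames(traits) <- NULL

  report <- NULL
  if (!is.null(reference)) {
    ref <- utils::read.csv(reference, stringsAsFactors = FALSE)
    common <- intersect(c("TRL_cm", "SA_cm2", "AD_cm", "RV_cm3", "PA_cm2"),
                        names(ref))
    report <- compare_traits(traits, ref, key = "filename", traits = common)
  }

  if (!is.null(out_csv)) {
    write_trait_csv(traits, out_csv, config = config,
                    length_rule = length_rule)
    if (!is.null(report)) {
      utils::write.csv(report,
                       sub("\\.csv$", "_report.csv", out_csv),
                       row.names = FALSE)
    }
  }

  list(traits = traits, report = report, skipped = skipped)
}

# CSV with run metadata as comment header lines + full-precision sidecar JSON
write_trait_csv <- function(traits, path, config, length_rule) {
  rounded <- traits
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], signif, digits = 6L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rootpheno %s", as.character(utils::packageVersion("rootpheno"))),
    sprintf("# method=%s median_kernel=%d block_size=%d offset_c=%g min_particle_area=%d connectivity=%d length_rule=%s",
            config$method, config$median_kernel, config$block_size,
            config$offset_c, config$min_particle_area, config$connectivity,
            length_rule)), con)
  utils::write.csv(traits, con, row.names = FALSE)
  jsonlite::write_json(
    list(version = as.character(utils::packageVersion("rootpheno")),
         config = unclass(config), length_rule = length_rule,
         traits = traits),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trait CSV written by [run_batch()]
#'
#' Skips the `#` metadata header lines.
#'
#' @param path CSV path.
#' @return a data frame.
#' @export
read_trait_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
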