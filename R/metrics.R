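#' Paired observed/reference series
#'
#' Container for agreement statistics: `observed` holds the algorithm's
#' values, `standard` the reference (ground truth or reference software).
#'
#' @param observed,standard equal-length numeric vectors.
#' @param trait_name optional label.
#' @return a `paired_series` object.
#' @export
paired_series <- function(observed, standard, trait_name = "") {
  observed <- as.numeric(observed)
  standard <- as.numeric(standard)
  if (length(observed) != length(standard)) {
    stop("`observed` and `standard` must have equal length", call. = FALSE)
  }
  if (length(observed) == 0L) {
    stop("empty series", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(standard)) {
    stop("series must not contain NA", call. = FALSE)
  }
  structure(list(observed = observed, standard = standard,
                 trait_name = trait_name, n = length(observed)),
            class = "paired_series")
}

as_paired <- function(p, standard = NULL, trait_name = "") {
  if (inherits(p, "paired_series")) p
  else paired_series(p, standard, trait_name)
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((observed - standard)^2))` over the paired series.
#'
#' @param p a [paired_series()], or a numeric vector of observed values.
#' @param standard reference values when `p` is a plain vector.
#' @return the RMSE.
#' @export
rmse <- function(p, standard = NULL) {
  p <- as_paired(p, standard)
  sqrt(mean((p$observed - p$standard)^2))
}

#' Mean bias error
#'
#' `MBE = mean(observed - standard)`.  Negative values mean the algorithm
#' underestimates the reference; positive values mean overestimation.
#'
#' @inheritParams rmse
#' @return the MBE.
#' @export
mbe <- function(p, standard = NULL) {
  p <- as_paired(p, standard)
  mean(p$observed - p$standard)
}

#' Coefficient of determination for paired measurements
#'
#' By default the squared Pearson correlation of the paired series, the
#' quantity usually quoted alongside 1:1 agreement plots.  With
#' `mode = "regression"` the coefficient of determination of the ordinary
#' least-squares fit of observed on standard (identical to Pearson-squared
#' for simple linear regression with intercept, provided for transparency).
#'
#' @inheritParams rmse
#' @param mode `"pearson"` (default) or `"regression"`.
#' @return R-squared in [0, 1].
#' @export
r_squared <- function(p, standard = NULL, mode = c("pearson", "regression")) {
  mode <- match.arg(mode)
  p <- as_paired(p, standard)
  if (p$n < 2L) stop("R-squared needs at least 2 pairs", call. = FALSE)
  if (stats::sd(p$observed) == 0 || stats::sd(p$standard) == 0) {
    stop("undefined correlation: a series is constant", call. = FALSE)
  }
  if (mode == "pearson") {
    return(stats::cor(p$observed, p$standard)^2)
  }
  fit <- stats::lm(observed ~ standard,
                   data = data.frame(observed = p$observed,
                                     standard = p$standard))
  summary(fit)$r.squared
}

#' Agreement report between two trait tables
#'
#' Joins an observed and a reference table on a key column and computes
#' RMSE, MBE and R-squared per trait column.
#'
#' @param observed,reference data frames sharing `key` and the trait
#'   columns.
#' @param key name of the join column (e.g. `"filename"`).
#' @param traits character vector of trait column names to compare.
#' @param r2_mode passed to [r_squared()].
#' @return a data frame with one row per trait: `trait`, `n`, `rmse`,
#'   `mbe`, `r_squared`.
#' @export
compare_traits <- function(observed, reference, key = "filename",
                           traits = c("TRL_cm", "SA_cm2", "AD_cm", "RV_cm3"),
                           r2_mode = c("pearson", "regression")) {
  r2_mode <- match.arg(r2_mode)
  stopifnot(key %in% names(observed), key %in% names(reference))
  missing_o <- setdiff(traits, names(observed))
  missing_r <- setdiff(traits, names(reference))
  if (length(missing_o) || length(missing_r)) {
    stop("trait columns missing: ",
         paste(unique(c(missing_o, missing_r)), collapse = ", "),
         call. = FALSE)
  }
  merged <- merge(observed[c(key, traits)], reference[c(key, traits)],
                  by = key, suffixes = c(".obs", ".ref"))
  if (nrow(merged) == 0L) stop("no keys in common", call. = FALSE)
  rows <- lapply(traits, function(tr) {
    p <- paired_series(merged[[paste0(tr, ".obs")]],
                       merged[[paste0(tr, ".ref")]], trait_name = tr)
    r2 <- tryCatch(r_squared(p, mode = r2_mode),
                   error = function(e) NA_real_)
    data.frame(trait = tr, n = p$n, rmse = rmse(p), mbe = mbe(p),
               r_squared = r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
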