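#' Fit a linear age trend to one visit series
#'
#' Ordinary least squares of feature value against age in days, with
#' intercept, for a single dog and feature. The residuals (observed minus
#' predicted, in age order) quantify how far each visit departs from the
#' dog's own growth trend; their mean square is the instability score
#' ([mse_score()]). Growth over the study window is approximated as
#' linear; detrending per dog neutralises breed- and individual-level
#' offsets.
#'
#' At least 3 visits are required: with 2 points the fit is exact and the
#' MSE degenerately zero, which would bias the instability score.
#'
#' @param age_days Integer vector of visit ages (strictly increasing).
#' @param value Numeric vector of day-averaged feature values.
#' @return An object of class `trend_fit`: list with `slope` (units/day),
#'   `intercept` (units), `residuals` (in age order), `mse`, `n`.
#' @export
#' @examples
#' fit <- fit_linear_trend(c(84, 112, 140), c(10, 12, 14))
#' fit$slope      # 1/14 units per day
#' fit$mse        # 0: collinear points
fit_linear_trend <- function(age_days, value) {
  n <- length(age_days)
  if (length(value) != n) {
    gv_abort("age_days and value must have equal length", "gv_config_error")
  }
  if (n < 3) {
    gv_abort("visit series too short to fit a trend (need >= 3 days)",
             "gv_degenerate_error")
  }
  x <- as.numeric(age_days)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    gv_abort("all visit ages equal: singular design", "gv_degenerate_error")
  }
  slope <- sum((x - mean(x)) * (value - mean(value))) / sxx
  intercept <- mean(value) - slope * mean(x)
  res <- value - (intercept + slope * x)
  structure(
    list(slope = slope, intercept = intercept, residuals = res,
         mse = mean(res^2), n = n),
    class = "trend_fit"
  )
}

#' Mean-square-error instability score
#'
#' The outcome measure: residuals from the dog's linear age trend are
#' squared, totalled, and averaged over the dog's visits. The divisor is
#' the visit count n, not n - 2; set `df_correct = TRUE` for the
#' degrees-of-freedom-corrected residual variance instead.
#'
#' @param fit A `trend_fit` from [fit_linear_trend()].
#' @param df_correct Divide by n - 2 instead of n (default `FALSE`).
#' @return Non-negative scalar.
#' @export
mse_score <- function(fit, df_correct = FALSE) {
  stopifnot(inherits(fit, "trend_fit"))
  ss <- sum(fit$residuals^2)
  if (df_correct) ss / (fit$n - 2) else ss / fit$n
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Linear age trend: slope %.6g /day, intercept %.6g (n = %d visits)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("MSE instability score: %.6g\n", x$mse))
  invisible(x)
}

#' Align a feature to a dog's pathological side
#'
#' Expresses lateralized and symmetry features relative to the
#' pathological limb. For a dog whose target side (its pathological side,
#' or `reference_side` for healthy dogs) differs from the reference side,
#' every non-axial feature is swapped with its mirrored counterpart
#' (`symmetry_pair` in the catalogue): a lateralized feature becomes its
#' contralateral twin, a symmetry feature its mirrored pair. Axial
#' features are unchanged for every dog. The mapping is an involution:
#' aligning twice returns the original feature.
#'
#' @param feature_id Feature id (vectorised).
#' @param pathological_side `"left"`, `"right"` or `"none"` (healthy);
#'   recycled against `feature_id`.
#' @param features Feature catalogue.
#' @param reference_side Side healthy dogs (and the output convention) are
#'   expressed in; default `"right"`.
#' @return Character vector of aligned feature ids.
#' @export
align_to_pathological_side <- function(feature_id, pathological_side,
                                       features,
                                       reference_side = c("right", "left")) {
  reference_side <- match.arg(reference_side)
  idx <- match(feature_id, features$feature_id)
  if (anyNA(idx)) {
    gv_abort(paste0("unknown feature(s): ",
                    paste(unique(feature_id[is.na(idx)]), collapse = ", ")),
             "gv_catalogue_error")
  }
  side <- ifelse(pathological_side == "none", reference_side,
                 pathological_side)
  lat <- features$laterality[idx]
  pair <- features$symmetry_pair[idx]
  swap <- side != reference_side & lat != "axial"
  if (any(swap & is.na(pair))) {
    bad <- unique(feature_id[swap & is.na(pair)])
    gv_abort(paste0("no mirrored counterpart in catalogue for: ",
                    paste(bad, collapse = ", ")), "gv_catalogue_error")
  }
  ifelse(swap, pair, feature_id)
}

#' Build the per-dog instability table
#'
#' For every dog and feature with a fittable visit series (>= `min_points`
#' distinct days), fits the linear age trend, computes the MSE instability
#' score, and aligns the feature id to the dog's pathological side. Series
#' that cannot be fitted (too short, degenerate) are logged and skipped,
#' never aborting the whole table.
#'
#' @param series Day-level series table (`dog_id`, `age_days`,
#'   `feature_id`, `value`) from [preprocess_runs()]/[filter_min_days()].
#' @param dogs Dog metadata from [read_dogs()].
#' @param features Feature catalogue.
#' @param reference_side Side convention for healthy dogs; see
#'   [align_to_pathological_side()].
#' @param min_points Minimum visits for a fittable series (default 3).
#' @param df_correct Passed to [mse_score()].
#' @return Tibble with one row per dog x aligned feature: `dog_id`,
#'   `diagnosis`, `feature_id` (aligned), `mse`, `n_days`, `slope`,
#'   `intercept`. Skipped series are attached as the `"skipped"`
#'   attribute (tibble `dog_id`, `feature_id`, `reason`).
#' @export
build_instability_table <- function(series, dogs, features,
                                    reference_side = "right",
                                    min_points = 3, df_correct = FALSE) {
  unknown_dogs <- setdiff(unique(series$dog_id), dogs$dog_id)
  if (length(unknown_dogs) > 0) {
    gv_abort(paste0("series references dog(s) missing from metadata: ",
                    paste(unknown_dogs, collapse = ", ")),
             "gv_integrity_error")
  }
  fits <- dplyr::summarise(
    dplyr::group_by(series, .data$dog_id, .data$feature_id),
    n_days = dplyr::n(),
    sxx = sum((.data$age_days - mean(.data$age_days))^2),
    sxy = sum((.data$age_days - mean(.data$age_days)) *
                (.data$value - mean(.data$value))),
    slope = dplyr::if_else(sxx > 0, sxy / sxx, NA_real_),
    intercept = mean(.data$value) - slope * mean(.data$age_days),
    ss_res = sum((.data$value - (intercept + slope * .data$age_days))^2),
    .groups = "drop"
  )
  ok <- fits$n_days >= min_points & fits$sxx > 0
  skipped <- tibble::tibble(
    dog_id = fits$dog_id[!ok],
    feature_id = fits$feature_id[!ok],
    reason = ifelse(fits$n_days[!ok] < min_points, "too_few_days",
                    "singular_design")
  )
  fits <- fits[ok, ]
  denom <- if (df_correct) fits$n_days - 2 else fits$n_days
  side <- dogs$pathological_side[match(fits$dog_id, dogs$dog_id)]
  out <- tibble::tibble(
    dog_id = fits$dog_id,
    diagnosis = dogs$diagnosis[match(fits$dog_id, dogs$dog_id)],
    feature_id = align_to_pathological_side(fits$feature_id, side, features,
                                            reference_side = reference_side),
    mse = fits$ss_res / denom,
    n_days = fits$n_days,
    slope = fits$slope,
    intercept = fits$intercept
  )
  out <- dplyr::arrange(out, .data$feature_id, .data$dog_id)
  attr(out, "skipped") <- skipped
  out
}
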