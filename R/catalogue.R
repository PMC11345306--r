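#' Default gait-feature catalogue
#'
#' The catalogue describes every gait feature the pipeline knows about:
#' display name, unit, which plausibility-bound category applies
#' (`energy`, `step_length`, `withers` or `none`), the side of the body the
#' feature refers to (`left`, `right` or `axial`), and the mirrored
#' counterpart used when aligning a dog's data to its pathological side.
#'
#' The default catalogue covers the thirteen analysed features of the
#' motivating serial IMU gait study of growing dogs (six pathological-limb
#' features encoded as explicit left/right variants, six limb-symmetry
#' features, and one axial hip-to-lumbar symmetry), plus the mirrored
#' counterparts required so that left/right mirroring is defined for every
#' non-axial feature. Users may supply their own catalogue in the same
#' format via [read_features()].
#'
#' @return A tibble with columns `feature_id`, `display_name`, `unit`,
#'   `exclusion_category`, `laterality`, `symmetry_pair`.
#' @export
#' @examples
#' default_feature_catalogue()
default_feature_catalogue <- function() {
  path <- system.file("extdata", "features.csv", package = "gaitvar",
                      mustWork = TRUE)
  read_features(path)
}

#' Published reference group summaries
#'
#' Group-level summary statistics (per-feature MSE instability scores:
#' mean and SD per diagnosis group, printed p-value, group sizes) reported
#' by the motivating serial IMU gait study for its 30 healthy and 14
#' hip-dysplastic dogs. The `primary` set contains the six features
#' directly affecting the pathological limb; the `additional` set the
#' seven remaining features. These summaries serve as inputs for
#' summary-statistic t-test verification (see [t_from_summary()]) and to
#' calibrate the synthetic-cohort simulator; the underlying raw data were
#' not deposited.
#'
#' @return A tibble with columns `feature_id`, `display_name`,
#'   `feature_set`, `p_printed`, `mean_healthy`, `sd_healthy`, `mean_hd`,
#'   `sd_hd`, `n_healthy`, `n_hd`.
#' @export
reference_group_summaries <- function() {
  path <- system.file("extdata", "reference_summaries.csv",
                      package = "gaitvar", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    feature_id = "c", display_name = "c", feature_set = "c",
    p_printed = "d", mean_healthy = "d", sd_healthy = "d",
    mean_hd = "d", sd_hd = "d", n_healthy = "i", n_hd = "i"
  ))
}

#' Plausibility bounds for gait features
#'
#' Fixed exclusion bounds per feature category. A value is implausible when
#' it is strictly greater than `upper` or less than or equal to `lower`;
#' independently, any measurement taken after `age_upper_days` days of age
#' is excluded. Defaults: energies (0, 200], step lengths (0.1 m, 0.6 m],
#' withers height (0.15 m, 0.6 m], age limit 450 d.
#'
#' @param energy,step_length,withers Numeric length-2 vectors
#'   `c(lower, upper)` overriding the default bounds for one category.
#' @param age_upper_days Upper age limit in days (measurements at greater
#'   age are excluded).
#' @return A list with a per-category bounds tibble (`bounds`) and the age
#'   limit (`age_upper_days`).
#' @export
#' @examples
#' exclusion_bounds()
exclusion_bounds <- function(energy = c(0, 200),
                             step_length = c(0.1, 0.6),
                             withers = c(0.15, 0.6),
                             age_upper_days = 450) {
  check_pair <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2 || x[2] <= x[1]) {
      gv_abort(sprintf("`%s` must be numeric c(lower, upper) with upper > lower", name),
               "gv_config_error")
    }
  }
  check_pair(energy, "energy")
  check_pair(step_length, "step_length")
  check_pair(withers, "withers")
  if (!is.numeric(age_upper_days) || length(age_upper_days) != 1 ||
      age_upper_days <= 0) {
    gv_abort("`age_upper_days` must be a positive number", "gv_config_error")
  }
  list(
    bounds = tibble::tibble(
      exclusion_category = c("energy", "step_length", "withers"),
      lower = c(energy[1], step_length[1], withers[1]),
      upper = c(energy[2], step_length[2], withers[2])
    ),
    age_upper_days = age_upper_days
  )
}

validate_features <- function(features) {
  required <- c("feature_id", "display_name", "unit", "exclusion_category",
                "laterality", "symmetry_pair")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) {
    gv_abort(paste0("feature catalogue misses column(s): ",
                    paste(missing, collapse = ", ")), "gv_parse_error")
  }
  if (anyDuplicated(features$feature_id)) {
    gv_abort("duplicate feature_id in catalogue", "gv_integrity_error")
  }
  bad_cat <- setdiff(unique(features$exclusion_category),
                     c("energy", "step_length", "withers", "none"))
  if (length(bad_cat) > 0) {
    gv_abort(paste0("unknown exclusion_category: ",
                    paste(bad_cat, collapse = ", ")), "gv_parse_error")
  }
  bad_lat <- setdiff(unique(features$laterality), c("left", "right", "axial"))
  if (length(bad_lat) > 0) {
    gv_abort(paste0("unknown laterality: ", paste(bad_lat, collapse = ", ")),
             "gv_parse_error")
  }
  # symmetry_pair must be symmetric: a -> b implies b -> a
  paired <- features[!is.na(features$symmetry_pair), ]
  if (nrow(paired) > 0) {
    unknown <- setdiff(paired$symmetry_pair, features$feature_id)
    if (length(unknown) > 0) {
      gv_abort(paste0("symmetry_pair refers to unknown feature(s): ",
                      paste(unknown, collapse = ", ")), "gv_integrity_error")
    }
    back <- features$symmetry_pair[match(paired$symmetry_pair, features$feature_id)]
    if (!all(back == paired$feature_id)) {
      gv_abort("symmetry_pair mapping is not symmetric", "gv_integrity_error")
    }
  }
  invisible(features)
}
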