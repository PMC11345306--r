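#' Read run-level gait measurements
#'
#' Reads the long-format run table: one row per dog, examination day, run
#' and feature. The expected dialect is comma-separated UTF-8 with header
#' `dog_id,age_days,run_index,feature_id,value`, `.` as decimal separator.
#' Age is expressed in integer days since birth; `run_index` numbers the
#' up-to-three consecutive walking trials of one examination day.
#'
#' Rows are either parsed or rejected with an error naming the offending
#' line; loading never silently drops data.
#'
#' @param path Path to a runs CSV file.
#' @return A tibble with columns `dog_id` (character), `age_days`
#'   (integer), `run_index` (integer), `feature_id` (character), `value`
#'   (double).
#' @export
read_runs <- function(path) {
  df <- read_strict(path,
                    cols = c("dog_id", "age_days", "run_index", "feature_id",
                             "value"),
                    types = readr::cols(
                      dog_id = "c", age_days = "i", run_index = "i",
                      feature_id = "c", value = "d"
                    ))
  if (nrow(df) > 0) {
    if (any(df$age_days <= 0)) {
      gv_abort("age_days must be positive", "gv_integrity_error")
    }
    if (!all(df$run_index %in% 1:3)) {
      gv_abort("run_index must be 1, 2 or 3", "gv_integrity_error")
    }
    key <- paste(df$dog_id, df$age_days, df$run_index, df$feature_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      gv_abort(paste0("duplicate (dog_id, age_days, run_index, feature_id): ",
                      dup), "gv_integrity_error")
    }
  }
  df
}

#' Read the dog metadata table
#'
#' Expected dialect: CSV with header
#' `dog_id,breed,diagnosis,pathological_side`; `diagnosis` is `healthy` or
#' `HD`; `pathological_side` is `left`/`right` for HD dogs and `none` for
#' healthy dogs. The diagnosis/side consistency invariant is enforced at
#' load time.
#'
#' @param path Path to a dogs CSV file.
#' @return A tibble with columns `dog_id`, `breed`, `diagnosis`,
#'   `pathological_side`.
#' @export
read_dogs <- function(path) {
  df <- read_strict(path,
                    cols = c("dog_id", "breed", "diagnosis",
                             "pathological_side"),
                    types = readr::cols(.default = "c"))
  if (anyDuplicated(df$dog_id)) {
    gv_abort("duplicate dog_id in dogs table", "gv_integrity_error")
  }
  bad_diag <- setdiff(unique(df$diagnosis), c("healthy", "HD"))
  if (length(bad_diag) > 0) {
    gv_abort(paste0("unknown diagnosis: ", paste(bad_diag, collapse = ", ")),
             "gv_parse_error")
  }
  bad_side <- setdiff(unique(df$pathological_side), c("left", "right", "none"))
  if (length(bad_side) > 0) {
    gv_abort(paste0("unknown pathological_side: ",
                    paste(bad_side, collapse = ", ")), "gv_parse_error")
  }
  inconsistent <- (df$diagnosis == "HD" & df$pathological_side == "none") |
    (df$diagnosis == "healthy" & df$pathological_side != "none")
  if (any(inconsistent)) {
    gv_abort(paste0("diagnosis/pathological_side inconsistent for dog(s): ",
                    paste(df$dog_id[inconsistent], collapse = ", ")),
             "gv_integrity_error")
  }
  df
}

#' Read a feature catalogue table
#'
#' Expected dialect: CSV with header
#' `feature_id,display_name,unit,exclusion_category,laterality,symmetry_pair`
#' (empty `symmetry_pair` for unpaired features). The catalogue is
#' validated: unique ids, known categories and lateralities, and a
#' symmetric `symmetry_pair` mapping.
#'
#' @param path Path to a features CSV file.
#' @return A validated catalogue tibble.
#' @seealso [default_feature_catalogue()]
#' @export
read_features <- function(path) {
  df <- read_strict(path,
                    cols = c("feature_id", "display_name", "unit",
                             "exclusion_category", "laterality",
                             "symmetry_pair"),
                    types = readr::cols(.default = "c"))
  validate_features(df)
}

#' Write and read the group-comparison results table
#'
#' `write_results()` writes one row per feature with group sizes, group
#' means and SDs of the MSE instability score, Shapiro-Wilk p-values per
#' group, the t statistic and its p-value, in a stable column order.
#' `read_results()` reads such a file back; write-then-read round-trips
#' values to full double precision (readr writes ~15 significant digits).
#'
#' @param comparisons A non-empty tibble of group comparisons as produced
#'   by [compare_all_features()].
#' @param path Output (input) CSV path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns the results tibble.
#' @export
write_results <- function(comparisons, path) {
  cols <- c("feature_id", "n_healthy", "n_hd", "mean_healthy", "sd_healthy",
            "mean_hd", "sd_hd", "shapiro_p_healthy", "shapiro_p_hd",
            "t_stat", "p_value")
  if (!is.data.frame(comparisons) || nrow(comparisons) == 0) {
    gv_abort("`comparisons` is empty: nothing to report", "gv_io_error")
  }
  missing <- setdiff(cols, names(comparisons))
  if (length(missing) > 0) {
    gv_abort(paste0("comparisons table misses column(s): ",
                    paste(missing, collapse = ", ")), "gv_io_error")
  }
  out <- comparisons[, cols]
  tryCatch(readr::write_csv(out, path),
           error = function(e) gv_abort(paste0("cannot write ", path, ": ",
                                               conditionMessage(e)),
                                        "gv_io_error"))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read_strict(path,
              cols = c("feature_id", "n_healthy", "n_hd", "mean_healthy",
                       "sd_healthy", "mean_hd", "sd_hd", "shapiro_p_healthy",
                       "shapiro_p_hd", "t_stat", "p_value"),
              types = readr::cols(feature_id = "c", n_healthy = "i",
                                  n_hd = "i", .default = "d"))
}

# Strict CSV reader: exact header, typed columns, any parse problem is an
# error that names the offending line (readr reports row numbers relative
# to the data, so +1 for the header).
read_strict <- function(path, cols, types) {
  if (!file.exists(path)) {
    gv_abort(paste0("file not found: ", path), "gv_io_error")
  }
  df <- suppressWarnings(
    readr::read_csv(path, col_types = types, progress = FALSE)
  )
  if (!identical(names(df), cols)) {
    gv_abort(paste0("unexpected header in ", path, "; expected: ",
                    paste(cols, collapse = ",")), "gv_parse_error")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    gv_abort(sprintf("malformed row in %s at line %d: expected %s, got '%s'",
                     path, probs$row[1], probs$expected[1], probs$actual[1]),
             "gv_parse_error")
  }
  # character NAs from truly empty mandatory fields
  mandatory <- setdiff(cols, "symmetry_pair")
  for (cl in mandatory) {
    if (anyNA(df[[cl]])) {
      gv_abort(sprintf("missing value in column '%s' of %s (line %d)",
                       cl, path, which(is.na(df[[cl]]))[1] + 1),
               "gv_parse_error")
    }
  }
  df
}
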