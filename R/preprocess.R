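#' Flag implausible run measurements
#'
#' Screens every run against the plausibility bounds of its feature's
#' exclusion category and against the age limit. A run is flagged iff its
#' value is strictly above the category's upper bound, at or below the
#' lower bound, or its `age_days` exceeds the age limit. Features of
#' category `none` are never value-flagged but are still age-checked.
#' The anomalies these bounds target originate in the upstream feature
#' extraction (e.g. step lengths of 2 m from doubly recorded stride
#' frequencies), so flagging feeds whole-day exclusion
#' ([drop_flagged_days()]) rather than single-row removal.
#'
#' @param runs Run table as returned by [read_runs()].
#' @param features Feature catalogue; every `feature_id` in `runs` must
#'   appear in it.
#' @param bounds Bounds specification from [exclusion_bounds()].
#' @return An exclusion log: tibble with columns `dog_id`, `age_days`,
#'   `reason` (`energy_bounds`, `step_length_bounds`, `withers_bounds` or
#'   `age_bound`), `feature_id`, `value`, one row per flagged run.
#' @export
flag_implausible <- function(runs, features, bounds = exclusion_bounds()) {
  unknown <- setdiff(unique(runs$feature_id), features$feature_id)
  if (length(unknown) > 0) {
    gv_abort(paste0("run table references unknown feature(s): ",
                    paste(unknown, collapse = ", ")), "gv_catalogue_error")
  }
  empty_log <- tibble::tibble(dog_id = character(), age_days = integer(),
                              reason = character(), feature_id = character(),
                              value = double())
  if (nrow(runs) == 0) return(empty_log)

  cat_of <- features$exclusion_category[match(runs$feature_id,
                                              features$feature_id)]
  b <- bounds$bounds
  lower <- b$lower[match(cat_of, b$exclusion_category)]
  upper <- b$upper[match(cat_of, b$exclusion_category)]
  value_bad <- !is.na(lower) & (runs$value > upper | runs$value <= lower)
  age_bad <- runs$age_days > bounds$age_upper_days

  log <- dplyr::bind_rows(
    tibble::tibble(dog_id = runs$dog_id[value_bad],
                   age_days = runs$age_days[value_bad],
                   reason = paste0(cat_of[value_bad], "_bounds"),
                   feature_id = runs$feature_id[value_bad],
                   value = runs$value[value_bad]),
    tibble::tibble(dog_id = runs$dog_id[age_bad],
                   age_days = runs$age_days[age_bad],
                   reason = "age_bound",
                   feature_id = runs$feature_id[age_bad],
                   value = runs$value[age_bad])
  )
  if (nrow(log) == 0) empty_log else
    dplyr::arrange(log, .data$dog_id, .data$age_days, .data$feature_id)
}

#' Drop whole examination days carrying flagged values
#'
#' For every (dog, day) pair present in the exclusion log, the entire data
#' series of that dog on that day — every feature, every run — is removed.
#' A single implausible value thus voids the complete measurement session,
#' reflecting that such anomalies implicate the session's feature
#' extraction as a whole.
#'
#' @param runs Run table.
#' @param log Exclusion log from [flag_implausible()] produced from the
#'   same runs.
#' @return The run table with all flagged dog-days removed.
#' @export
drop_flagged_days <- function(runs, log) {
  if (nrow(log) == 0) return(runs)
  bad <- unique(paste(log$dog_id, log$age_days))
  keep <- !(paste(runs$dog_id, runs$age_days) %in% bad)
  runs[keep, ]
}

#' Average replicate runs within one examination day
#'
#' Collapses the 1-3 consecutive walking trials of one examination day to
#' their arithmetic mean, per dog and feature.
#'
#' @param runs Run table, already cleaned by [drop_flagged_days()].
#' @return A day-level tibble with columns `dog_id`, `age_days`,
#'   `feature_id`, `value` (the day mean).
#' @export
average_runs_per_day <- function(runs) {
  dplyr::summarise(
    dplyr::group_by(runs, .data$dog_id, .data$age_days, .data$feature_id),
    value = mean(.data$value), .groups = "drop"
  )
}

#' Remove dogs with too few measurement days
#'
#' A dog's measurement-day count is its number of distinct surviving
#' examination days (across features, not per feature): a feature missing
#' on some days is tolerated and simply yields a shorter series. Dogs
#' below `min_days` are removed entirely.
#'
#' @param day_records Day-level table from [average_runs_per_day()].
#' @param min_days Minimum number of distinct measurement days (default 4).
#' @return A list with `series` (the surviving day-level records, sorted
#'   by dog, feature and age — each dog-feature group is one visit series)
#'   and `removed_dogs` (character vector of removed dog ids).
#' @export
filter_min_days <- function(day_records, min_days = 4) {
  if (nrow(day_records) == 0) {
    return(list(series = day_records, removed_dogs = character()))
  }
  days_per_dog <- dplyr::summarise(
    dplyr::group_by(day_records, .data$dog_id),
    n_days = dplyr::n_distinct(.data$age_days), .groups = "drop"
  )
  removed <- days_per_dog$dog_id[days_per_dog$n_days < min_days]
  series <- day_records[!(day_records$dog_id %in% removed), ]
  series <- dplyr::arrange(series, .data$dog_id, .data$feature_id,
                           .data$age_days)
  list(series = series, removed_dogs = sort(removed))
}

#' Full preprocessing stage
#'
#' Convenience wrapper chaining [flag_implausible()],
#' [drop_flagged_days()], [average_runs_per_day()] and
#' [filter_min_days()], and reporting stage-by-stage row counts so that
#' the conservation identity (rows in = rows kept + rows on excluded days
#' + rows of removed dogs) can be verified.
#'
#' @inheritParams flag_implausible
#' @inheritParams filter_min_days
#' @return A list: `series`, `exclusions` (the log), `removed_dogs`, and
#'   `counts` (named integer vector of rows at each stage).
#' @export
preprocess_runs <- function(runs, features, bounds = exclusion_bounds(),
                            min_days = 4) {
  log <- flag_implausible(runs, features, bounds)
  kept <- drop_flagged_days(runs, log)
  day_records <- average_runs_per_day(kept)
  filtered <- filter_min_days(day_records, min_days = min_days)
  # a dog whose every day was excluded has zero measurement days left and
  # falls to the same rule even though no day record remains to count
  vanished <- setdiff(unique(runs$dog_id), unique(kept$dog_id))
  removed_dogs <- sort(union(filtered$removed_dogs, vanished))
  removed_day_rows <- nrow(runs) - nrow(kept)
  removed_dog_rows <- sum(kept$dog_id %in% removed_dogs)
  list(
    series = filtered$series,
    exclusions = log,
    removed_dogs = removed_dogs,
    counts = c(rows_in = nrow(runs),
               rows_on_excluded_days = removed_day_rows,
               rows_of_removed_dogs = removed_dog_rows,
               rows_kept = nrow(kept) - removed_dog_rows,
               day_records = nrow(filtered$series))
  )
}
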