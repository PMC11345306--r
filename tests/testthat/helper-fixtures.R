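# Small in-code fixtures shared across the suite.

tiny_catalogue <- function() {
  tibble::tibble(
    feature_id = c("len_r", "len_l", "angle_r", "angle_l", "axial_sym",
                   "energy_r"),
    display_name = c("Step length (right)", "Step length (left)",
                     "Angle (right)", "Angle (left)", "Axial symmetry",
                     "Energy (right)"),
    unit = c("m", "m", "deg", "deg", "%", "a.u."),
    exclusion_category = c("step_length", "step_length", "none", "none",
                           "none", "energy"),
    laterality = c("right", "left", "right", "left", "axial", "right"),
    symmetry_pair = c("len_l", "len_r", "angle_l", "angle_r", NA, NA)
  )
}

tiny_dogs <- function() {
  tibble::tibble(
    dog_id = c("d1", "d2", "d3", "d4"),
    breed = c("Australian Shepherd", "Golden Retriever", "Rottweiler",
              "Australian Shepherd"),
    diagnosis = c("healthy", "HD", "HD", "healthy"),
    pathological_side = c("none", "left", "right", "none")
  )
}

# a clean run table: `days` visits, one feature, one run per day
runs_for <- function(dog_id, feature_id, days, values, run_index = 1L) {
  tibble::tibble(dog_id = dog_id, age_days = as.integer(days),
                 run_index = as.integer(run_index),
                 feature_id = feature_id, value = values)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

tiny_params <- function() {
  tibble::tibble(
    feature_id = tiny_catalogue()$feature_id,
    intercept = c(0.3, 0.3, 20, 20, 100, 100),
    slope = c(2e-4, 2e-4, 0.02, 0.02, 0, 0.05),
    run_sd = c(0.005, 0.005, 0.3, 0.3, 1, 2),
    sigma_healthy = c(0.02, 0.02, 1, 1, 3, 5),
    sigma_hd = c(0.03, 0.03, 1.5, 1.5, 4, 6)
  )
}

# single-feature null configuration used for fast whole-pipeline runs
null_config <- function(seed, sigma_hd = 1, n_dogs = 44, n_hd = 14) {
  feat <- tibble::tibble(feature_id = "f1", display_name = "F1", unit = "u",
                         exclusion_category = "none", laterality = "axial",
                         symmetry_pair = NA_character_)
  fp <- tibble::tibble(feature_id = "f1", intercept = 10, slope = 0.01,
                       run_sd = 0.3, sigma_healthy = 1, sigma_hd = sigma_hd)
  cohort_config(n_dogs = n_dogs, n_hd = n_hd, features = feat,
                feature_params = fp, seed = seed)
}
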