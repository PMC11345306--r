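#!/usr/bin/env Rscript
# Per dog and feature: fit the linear age trend, score instability as the
# mean squared residual (MSE), and align feature identities to the
# pathological side (mirroring symmetry features for left-affected dogs).
# Writes results/instability/instability.csv.

suppressMessages(library(gaitvar))
out_dir <- "results/instability"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

series <- readr::read_csv("results/preprocessed/series.csv",
                          col_types = readr::cols(dog_id = "c",
                                                  age_days = "i",
                                                  feature_id = "c",
                                                  value = "d"))
dogs <- read_dogs("results/cohort/dogs.csv")
features <- read_features("results/cohort/features.csv")

instab <- build_instability_table(series, dogs, features,
                                  reference_side = "right")
readr::write_csv(instab, file.path(out_dir, "instability.csv"))
skipped <- attr(instab, "skipped")
if (nrow(skipped) > 0) {
  readr::write_csv(skipped, file.path(out_dir, "skipped_series.csv"))
}
cat(sprintf("Fitted %d dog-feature trends for %d dogs (%d series skipped as unfittable).\n",
            nrow(instab), length(unique(instab$dog_id)), nrow(skipped)))
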