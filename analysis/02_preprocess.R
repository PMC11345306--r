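#!/usr/bin/env Rscript
# Preprocess the simulated cohort: flag implausible values against the
# plausibility bounds, exclude the whole dog-day a flagged value belongs
# to, average the up-to-3 runs of each day, and drop dogs with fewer than
# 4 measurement days. Writes the exclusion log, the per-dog day-level
# series and a manifest whose counts satisfy the conservation identity
# rows_in = rows_kept + rows_on_excluded_days + rows_of_removed_dogs.

suppressMessages(library(gaitvar))
in_dir <- "results/cohort"
out_dir <- "results/preprocessed"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

runs <- read_runs(file.path(in_dir, "runs.csv"))
features <- read_features(file.path(in_dir, "features.csv"))

pre <- preprocess_runs(runs, features)

readr::write_csv(pre$exclusions, file.path(out_dir, "exclusions.csv"))
readr::write_csv(pre$series, file.path(out_dir, "series.csv"))
writeLines(pre$removed_dogs, file.path(out_dir, "removed_dogs.txt"))
readr::write_csv(
  data.frame(key = names(pre$counts), value = unname(pre$counts)),
  file.path(out_dir, "manifest.csv")
)

stopifnot(pre$counts[["rows_in"]] ==
            pre$counts[["rows_kept"]] +
            pre$counts[["rows_on_excluded_days"]] +
            pre$counts[["rows_of_removed_dogs"]])
cat(sprintf("Of %d rows, %d sat on excluded days and %d belonged to the %d dogs removed by the 4-day rule; %d day-level records remain.\n",
            pre$counts[["rows_in"]], pre$counts[["rows_on_excluded_days"]],
            pre$counts[["rows_of_removed_dogs"]],
            length(pre$removed_dogs), pre$counts[["day_records"]]))
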