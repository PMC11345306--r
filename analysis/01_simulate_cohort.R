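#!/usr/bin/env Rscript
# Simulate the study cohort: 44 dogs (14 HD), monthly visits from 12 to 28
# weeks of age then bimonthly to ~15 months, 1-3 walking trials per visit,
# 13 gait features (plus mirrored counterparts) with linear growth trends
# and HD-inflated dispersion on the pathological side. A small fraction of
# dog-days receives an injected implausible value (e.g. a 2 m step length)
# to exercise the plausibility filter downstream.
#
# Writes results/cohort/{runs,dogs,features,truth}.csv and a manifest.

suppressMessages(library(gaitvar))
seed <- 20240730L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(implausible_rate = 0.05, seed = seed)
sim <- simulate_cohort(cfg)

readr::write_csv(sim$runs, file.path(out_dir, "runs.csv"))
readr::write_csv(sim$dogs, file.path(out_dir, "dogs.csv"))
readr::write_csv(sim$features, file.path(out_dir, "features.csv"), na = "")
readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))

manifest <- data.frame(
  key = c("seed", "n_dogs", "n_hd", "n_features", "n_runs",
          "n_injected_days"),
  value = c(seed, nrow(sim$dogs), sum(sim$dogs$diagnosis == "HD"),
            nrow(sim$features), nrow(sim$runs), nrow(sim$truth))
)
readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

cat(sprintf("Simulated %d dogs (%d HD) at seed %d: %d run-level rows, %d dog-days with an injected anomaly.\n",
            nrow(sim$dogs), sum(sim$dogs$diagnosis == "HD"), seed,
            nrow(sim$runs), nrow(sim$truth)))
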