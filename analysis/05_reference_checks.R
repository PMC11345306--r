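#!/usr/bin/env Rscript
# Verify the published group-level tables by recomputing pooled t-tests
# from the printed summary statistics (the raw study data were not
# deposited, so this is the only reproducible route to the printed
# p-values). Writes results/reference/summary_ttests.csv.

suppressMessages(library(gaitvar))
out_dir <- "results/reference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ref <- reference_group_summaries()
tt <- lapply(seq_len(nrow(ref)), function(i) {
  out <- t_from_summary(ref$mean_healthy[i], ref$sd_healthy[i],
                        ref$n_healthy[i], ref$mean_hd[i], ref$sd_hd[i],
                        ref$n_hd[i])
  data.frame(feature_id = ref$feature_id[i],
             feature_set = ref$feature_set[i],
             p_printed = ref$p_printed[i],
             t_recomputed = out$t_stat, p_recomputed = out$p_value)
})
tt <- do.call(rbind, tt)
readr::write_csv(tt, file.path(out_dir, "summary_ttests.csv"))

cat("Recomputed pooled t-tests from the printed group summaries:\n")
print(transform(tt, p_recomputed = signif(p_recomputed, 2)),
      row.names = FALSE)
cat(sprintf("\nExtension: printed p 3.1e-03, recomputed %.2g.\n",
            tt$p_recomputed[tt$feature_id == "extension_r"]))
cat(sprintf("Pathological-limb features with recomputed p < 0.01: %d of 6.\n",
            sum(tt$p_recomputed[tt$feature_set == "primary"] < 0.01)))
cat(sprintf("Features with a higher HD group mean: %d of %d.\n",
            sum(ref$mean_hd > ref$mean_healthy), nrow(ref)))
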