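#!/usr/bin/env Rscript
# Healthy-vs-HD comparison of the MSE instability scores, per aligned
# feature: group summaries, Shapiro-Wilk normality p-values, pooled
# two-sample t-tests at alpha = 0.05, box-whisker data with 1.5 IQR
# whiskers, and the annotated box-whisker figure for the six
# pathological-limb features.
#
# Writes results/comparison/{results.csv,boxplot_data.csv,boxplots.pdf}.

suppressMessages(library(gaitvar))
out_dir <- "results/comparison"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

instab <- readr::read_csv("results/instability/instability.csv",
                          col_types = readr::cols(dog_id = "c",
                                                  diagnosis = "c",
                                                  feature_id = "c",
                                                  .default = "d"))
features <- read_features("results/cohort/features.csv")

cmp <- compare_all_features(instab, alpha = 0.05)
write_results(cmp, file.path(out_dir, "results.csv"))

primary <- c("extension_r", "step_length_r", "max_acc_amp_r",
             "ventral_acc_r", "max_gyr_amp_r", "acc_sd_r")
box <- export_boxplot_data(instab, primary, comparisons = cmp,
                           catalogue = features)
readr::write_csv(box$data, file.path(out_dir, "boxplot_data.csv"))
ggplot2::ggsave(file.path(out_dir, "boxplots.pdf"), box$plot,
                width = 9, height = 6)

shown <- cmp[cmp$feature_id %in% primary, ]
shown$stars <- significance_stars(shown$p_value)
cat("Pathological-limb features, healthy vs HD MSE:\n")
print(as.data.frame(shown[, c("feature_id", "mean_healthy", "mean_hd",
                              "t_stat", "p_value", "stars")]),
      digits = 3, row.names = FALSE)
cat(sprintf("%d of %d aligned features significant at 0.05.\n",
            sum(cmp$significant), nrow(cmp)))
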