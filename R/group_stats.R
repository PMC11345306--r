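#' Shapiro-Wilk normality p-value
#'
#' Thin, validating wrapper around [stats::shapiro.test()] used to check
#' whether per-group MSE instability scores are compatible with a normal
#' distribution before the t-test.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all identical.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) {
    gv_abort("Shapiro-Wilk needs at least 3 observations",
             "gv_degenerate_error")
  }
  if (diff(range(values)) == 0) {
    gv_abort("Shapiro-Wilk undefined for a constant sample",
             "gv_degenerate_error")
  }
  shapiro.test(values)$p.value
}

#' Unpaired two-sample t-test
#'
#' Two-sided comparison of two independent groups. The default is the
#' pooled-variance Student t-test with n_a + n_b - 2 degrees of freedom,
#' which is the form that reproduces the reference study's printed
#' p-values from its group summaries; `var_equal = FALSE` gives Welch's
#' unequal-variance test instead.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled variance (default `TRUE`) or Welch.
#' @return A list with `t_stat`, `p_value`, `significant`, `df`.
#' @export
two_sample_t <- function(values_a, values_b, alpha = 0.05, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    gv_abort("each group needs at least 2 observations", "gv_degenerate_error")
  }
  ht <- t.test(values_a, values_b, var.equal = var_equal,
               alternative = "two.sided")
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, df = unname(ht$parameter))
}

#' Pooled t-test from group summary statistics
#'
#' Computes the two-sided pooled-variance Student t-test directly from
#' group means, SDs and sizes, algebraically identical to [two_sample_t()]
#' applied to any raw data having those summaries. Used to verify
#' published group-level tables when the raw data are unavailable.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return A list with `t_stat`, `p_value`, `df`.
#' @export
#' @examples
#' # healthy vs HD extension-instability summaries of the reference study
#' t_from_summary(2.03, 0.74, 30, 2.91, 1.10, 14)
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) {
    gv_abort("each group needs n >= 2", "gv_degenerate_error")
  }
  if (sd_a < 0 || sd_b < 0) {
    gv_abort("standard deviations must be non-negative", "gv_config_error")
  }
  if (sd_a == 0 && sd_b == 0 && mean_a == mean_b) {
    gv_abort("t statistic undefined: both SDs zero and equal means",
             "gv_degenerate_error")
  }
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t_stat <- (mean_a - mean_b) / se
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df), df = df)
}

#' Compare healthy and HD groups for every feature
#'
#' For each aligned feature in an instability table, computes group sizes,
#' group means and SDs of the MSE score, Shapiro-Wilk normality p per
#' group, and the unpaired t-test. Features lacking one diagnosis group or
#' with too few dogs are reported with `NA` statistics and a note, never
#' silently dropped. A failed normality check attaches a warning note but
#' does not switch the test to a nonparametric alternative; no
#' multiple-testing correction is applied by default (both choices mirror
#' the reference analysis; `p_adjust` enables Holm/Bonferroni and the
#' adjusted values are used for the significance call).
#'
#' @param instability Instability table from [build_instability_table()].
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled (default) or Welch t-test.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Tibble with one row per feature: the `results.csv` columns
#'   (`feature_id`, `n_healthy`, `n_hd`, `mean_healthy`, `sd_healthy`,
#'   `mean_hd`, `sd_hd`, `shapiro_p_healthy`, `shapiro_p_hd`, `t_stat`,
#'   `p_value`) plus `significant` and `note`.
#' @export
compare_all_features <- function(instability, alpha = 0.05, var_equal = TRUE,
                                 p_adjust = "none") {
  stopifnot(all(c("feature_id", "diagnosis", "mse") %in% names(instability)))
  grp <- function(fid, diag) {
    instability$mse[instability$feature_id == fid &
                      instability$diagnosis == diag]
  }
  shapiro_or_na <- function(x) {
    if (length(x) >= 3 && length(x) <= 5000 && diff(range(x)) > 0) {
      shapiro.test(x)$p.value
    } else NA_real_
  }
  rows <- lapply(unique(instability$feature_id), function(fid) {
    h <- grp(fid, "healthy")
    d <- grp(fid, "HD")
    note <- ""
    t_stat <- p_value <- NA_real_
    if (length(h) < 2 || length(d) < 2) {
      note <- "missing or undersized group; no test performed"
    } else if (sd(h) == 0 && sd(d) == 0) {
      note <- "degenerate: zero variance in both groups"
    } else {
      tt <- two_sample_t(h, d, alpha = alpha, var_equal = var_equal)
      t_stat <- tt$t_stat
      p_value <- tt$p_value
    }
    sp_h <- shapiro_or_na(h)
    sp_d <- shapiro_or_na(d)
    if (!is.na(p_value) && ((!is.na(sp_h) && sp_h < alpha) ||
                            (!is.na(sp_d) && sp_d < alpha))) {
      note <- paste0(note, ifelse(nzchar(note), "; ", ""),
                     "Shapiro-Wilk indicates non-normal MSE distribution")
    }
    tibble::tibble(
      feature_id = fid,
      n_healthy = length(h), n_hd = length(d),
      mean_healthy = if (length(h)) mean(h) else NA_real_,
      sd_healthy = if (length(h) > 1) sd(h) else NA_real_,
      mean_hd = if (length(d)) mean(d) else NA_real_,
      sd_hd = if (length(d) > 1) sd(d) else NA_real_,
      shapiro_p_healthy = sp_h, shapiro_p_hd = sp_d,
      t_stat = t_stat, p_value = p_value, note = note
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out[, c("feature_id", "n_healthy", "n_hd", "mean_healthy", "sd_healthy",
          "mean_hd", "sd_hd", "shapiro_p_healthy", "shapiro_p_hd",
          "t_stat", "p_value", "significant", "note")]
}

#' Significance stars for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, empty
#' otherwise (vectorised).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Box-whisker summary of group MSE distributions
#'
#' Per feature and diagnosis group: five-number summary with quartiles by
#' linear interpolation ([stats::quantile()] type 7), whiskers at the most
#' extreme points within 1.5 IQR of the quartiles, and the outlier count.
#' Also builds the healthy-vs-HD box-whisker figure (healthy left, HD
#' right) annotated with significance stars from the accompanying group
#' comparison.
#'
#' @param instability Instability table.
#' @param features Character vector of aligned feature ids to plot.
#' @param comparisons Optional result of [compare_all_features()] used for
#'   the star annotations.
#' @param catalogue Optional feature catalogue for display names.
#' @return A list with `data` (tidy tibble: `feature_id`, `group`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`, `whisker_lo`, `whisker_hi`,
#'   `n_outliers`) and `plot` (a ggplot object).
#' @export
export_boxplot_data <- function(instability, features,
                                comparisons = NULL, catalogue = NULL) {
  if (length(features) == 0) {
    gv_abort("no features selected", "gv_config_error")
  }
  unknown <- setdiff(features, unique(instability$feature_id))
  if (length(unknown) > 0) {
    gv_abort(paste0("feature(s) absent from the instability table: ",
                    paste(unknown, collapse = ", ")), "gv_catalogue_error")
  }
  five_num <- function(x) {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    tibble::tibble(
      n = length(x), min = min(x), q1 = q[1], median = q[2], q3 = q[3],
      max = max(x), whisker_lo = min(inside), whisker_hi = max(inside),
      n_outliers = sum(x < lo_fence | x > hi_fence)
    )
  }
  rows <- list()
  for (fid in features) {
    for (g in c("healthy", "HD")) {
      x <- instability$mse[instability$feature_id == fid &
                             instability$diagnosis == g]
      if (length(x) == 0) {
        warn(sprintf("feature '%s': empty %s group, skipped", fid, g))
        next
      }
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(tibble::tibble(feature_id = fid, group = g),
                         five_num(x))
    }
  }
  data <- dplyr::bind_rows(rows)

  plot_df <- instability[instability$feature_id %in% features, ]
  plot_df$group <- factor(plot_df$diagnosis, levels = c("healthy", "HD"))
  if (!is.null(catalogue)) {
    lbl <- catalogue$display_name[match(features, catalogue$feature_id)]
    lbl[is.na(lbl)] <- features[is.na(lbl)]
    plot_df$panel <- factor(plot_df$feature_id, levels = features,
                            labels = lbl)
  } else {
    plot_df$panel <- factor(plot_df$feature_id, levels = features)
  }
  p <- ggplot2::ggplot(plot_df,
                       ggplot2::aes(x = .data$group, y = .data$mse)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 1) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "MSE instability score") +
    ggplot2::theme_bw()
  if (!is.null(comparisons)) {
    stars <- comparisons[comparisons$feature_id %in% features, ]
    stars$label <- significance_stars(stars$p_value)
    stars <- stars[nzchar(stars$label), ]
    if (nrow(stars) > 0) {
      tops <- dplyr::summarise(dplyr::group_by(plot_df, .data$panel,
                                               .data$feature_id),
                               y = max(.data$mse) * 1.06, .groups = "drop")
      ann <- dplyr::inner_join(stars, tops, by = "feature_id")
      p <- p + ggplot2::geom_text(
        data = ann,
        ggplot2::aes(x = 1.5, y = .data$y, label = .data$label),
        inherit.aes = FALSE, size = 5
      )
    }
  }
  list(data = data, plot = p)
}
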