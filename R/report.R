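## Three-decimal p formatting used throughout the plain-text summary;
## very small values print as "<0.001".
format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p)))
}

regression_table_df <- function(reg) {
  cbind(reg$table,
        r_squared_selected = reg$r_squared,
        r_squared_full = reg$r_squared_full)
}

#' Render a result bundle to files
#'
#' Writes the bundle's tables as CSV, the whole bundle as JSON, and a
#' plain-text summary that mirrors the mean +- SD / 3-decimal-p
#' presentation of a clinical cohort report.  Output is deterministic:
#' rendering the same bundle twice produces identical files.
#'
#' @param bundle A `cohort_result_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @param figures Also write PNG figures of the group-mean normalized
#'   spectra and the per-electrode alpha-ratio distributions (default
#'   FALSE; figures are not part of the byte-determinism contract).
#' @return Character vector of written file paths, invisibly.
#' @export
render_report <- function(bundle, dir, figures = FALSE) {
  if (!inherits(bundle, "cohort_result_bundle")) {
    stop("expected a cohort_result_bundle")
  }
  required <- c("cohort", "features", "demographics", "cpt", "eeg_features",
                "group_spectra", "freq_tests", "correlations",
                "regression_commission", "regression_omission", "provenance")
  missing <- required[vapply(required, function(b) is.null(bundle[[b]]),
                             logical(1))]
  if (length(missing)) {
    stop("incomplete bundle; missing block(s): ", paste(missing, collapse = ", "))
  }
  if (!nrow(bundle$cohort) || length(unique(bundle$cohort$group)) < 2) {
    stop("refusing to render: bundle has an empty group")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wcsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wcsv(bundle$cohort, "cohort.csv")
  wcsv(bundle$features, "features.csv")
  wcsv(bundle$demographics, "demographics.csv")
  wcsv(bundle$cpt, "cpt_comparison.csv")
  wcsv(bundle$eeg_features, "eeg_feature_comparison.csv")
  wcsv(bundle$group_spectra, "group_spectra.csv")
  wcsv(bundle$freq_tests, "per_frequency_tests.csv")
  wcsv(bundle$correlations, "correlations.csv")
  wcsv(regression_table_df(bundle$regression_commission), "regression_commission.csv")
  wcsv(regression_table_df(bundle$regression_omission), "regression_omission.csv")

  jp <- file.path(dir, "bundle.json")
  json_bundle <- list(
    provenance = bundle$provenance,
    demographics = bundle$demographics,
    cpt = bundle$cpt,
    eeg_features = bundle$eeg_features,
    correlations = bundle$correlations,
    regression_commission = regression_table_df(bundle$regression_commission),
    regression_omission = regression_table_df(bundle$regression_omission)
  )
  jsonlite::write_json(json_bundle, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  paths <- c(paths, jp)

  sp <- file.path(dir, "summary.txt")
  con <- file(sp, "w")
  writeLines(render_summary_lines(bundle), con)
  close(con)
  paths <- c(paths, sp)

  if (figures) paths <- c(paths, render_figures(bundle, dir))
  invisible(paths)
}

render_summary_lines <- function(bundle) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  comp_lines <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("  %-22s %12s %12s   p = %s", df$variable[i], df$summary_a[i],
              df$summary_b[i], format_p(df$p_value[i]))
    }, character(1))
  }
  groups <- unique(bundle$cohort$group)
  add("Cohort analysis summary (%s mode, seed %d)",
      bundle$provenance$mode, bundle$provenance$seed)
  add("Groups: %s (values are mean +- SD or counts; two-sided p)",
      paste(groups, collapse = " vs "))
  add("")
  add("Demographics")
  ln <- c(ln, comp_lines(bundle$demographics))
  add("")
  add("CPT T-scores")
  ln <- c(ln, comp_lines(bundle$cpt))
  add("")
  add("Resting EEG features and alpha ratios (%s mode)",
      bundle$provenance$ratio_mode)
  ln <- c(ln, comp_lines(bundle$eeg_features))
  add("")
  add("Spearman correlation of the %s alpha ratio with CPT T-scores",
      bundle$provenance$ratio_electrode)
  for (i in seq_len(nrow(bundle$correlations))) {
    add("  %-22s rho = %6.3f   p = %s", bundle$correlations$variable[i],
        bundle$correlations$rho[i], format_p(bundle$correlations$p_value[i]))
  }
  add("")
  reg_lines <- function(reg, outcome) {
    add("Stepwise regression: %s T-score (full-entry coefficients)", outcome)
    for (i in seq_len(nrow(reg$table))) {
      add("  %-14s B = %8.2f   t = %6.2f   p = %s%s",
          reg$table$predictor[i], reg$table$B_full[i], reg$table$t_full[i],
          format_p(reg$table$p_full[i]),
          if (reg$table$selected[i]) "   [selected]" else "")
    }
    add("  selected model R^2 = %.3f (full %.3f)", reg$r_squared,
        reg$r_squared_full)
  }
  reg_lines(bundle$regression_commission, "commission")
  add("")
  reg_lines(bundle$regression_omission, "omission")
  ln
}

## Base-graphics figures; deliberately simple.
render_figures <- function(bundle, dir) {
  gs <- bundle$group_spectra
  p1 <- file.path(dir, "group_spectra.png")
  grDevices::png(p1, width = 1400, height = 500 * length(unique(gs$channel)),
                 res = 120)
  graphics::par(mfrow = c(length(unique(gs$channel)), 2))
  for (ch in unique(gs$channel)) {
    for (sess in unique(gs$session)) {
      sub <- gs[gs$channel == ch & gs$session == sess, ]
      groups <- unique(sub$group)
      graphics::plot(NULL, xlim = range(sub$freq), ylim = c(0, max(sub$mean) * 1.1),
                     xlab = "frequency (Hz)", ylab = "normalized power",
                     main = sprintf("%s - %s", ch, sess))
      for (k in seq_along(groups)) {
        g <- sub[sub$group == groups[k], ]
        graphics::lines(g$freq, g$mean, col = k + 1, lwd = 2)
      }
      graphics::legend("topright", legend = groups, col = seq_along(groups) + 1,
                       lwd = 2, bty = "n")
    }
  }
  grDevices::dev.off()

  p2 <- file.path(dir, "alpha_ratios.png")
  grDevices::png(p2, width = 1200, height = 450, res = 120)
  feats <- merge(bundle$features,
                 bundle$cohort[, c("id", "group")], by = "id")
  chans <- unique(feats$channel)
  graphics::par(mfrow = c(1, length(chans)))
  for (ch in chans) {
    sub <- feats[feats$channel == ch, ]
    graphics::boxplot(alpha_ratio ~ group, data = sub,
                      main = sprintf("alpha ratio - %s", ch),
                      ylab = "attention / resting alpha power")
    graphics::stripchart(alpha_ratio ~ group, data = sub, add = TRUE,
                         vertical = TRUE, pch = 19, method = "jitter")
  }
  grDevices::dev.off()
  c(p1, p2)
}
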