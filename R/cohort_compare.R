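## Continuous row: mean +- SD per group, Mann-Whitney p.
compare_continuous <- function(variable, a, b) {
  mw <- mann_whitney(a, b)
  data.frame(variable = variable, type = "continuous",
             summary_a = sprintf("%.1f ± %.1f", mean(a), stats::sd(a)),
             summary_b = sprintf("%.1f ± %.1f", mean(b), stats::sd(b)),
             mean_a = mean(a), sd_a = stats::sd(a),
             mean_b = mean(b), sd_b = stats::sd(b),
             test = "Mann-Whitney", statistic = mw$statistic,
             p_value = mw$p_value, stringsAsFactors = FALSE)
}

## Categorical row: yes-counts per group, chi-square on the 2x2 table.
compare_binary <- function(variable, a, b, correct = FALSE) {
  tab <- rbind(c(sum(a), sum(!a)), c(sum(b), sum(!b)))
  cs <- chi_square_2x2(tab, correct = correct)
  data.frame(variable = variable, type = "categorical",
             summary_a = sprintf("%d/%d", sum(a), sum(!a)),
             summary_b = sprintf("%d/%d", sum(b), sum(!b)),
             mean_a = sum(a), sd_a = NA_real_, mean_b = sum(b), sd_b = NA_real_,
             test = if (correct) "chi-square (Yates)" else "chi-square",
             statistic = cs$statistic, p_value = cs$p_value,
             stringsAsFactors = FALSE)
}

#' Group comparison tables for a cohort
#'
#' Produces the demographic and behavioral group-comparison tables for a
#' two-group cohort: per variable, mean +- SD (or counts) in each group and
#' the designated two-sided test -- Mann-Whitney U for continuous
#' variables, Pearson chi-square for categorical ones.  EEG feature
#' columns (`tbr_*`, `total_power_*`, `alpha_ratio_*`), when present, are
#' compared the same way.
#'
#' @param cohort Data.frame with at least `group` (values `PWS`/`control`
#'   or any two levels; the first level alphabetically-last is taken as the
#'   patient group if named `PWS`), `age`, `sex`, `bmi`, `bmi_z`,
#'   `intelligence`, and `cpt_*` T-score columns.
#' @param chi_correct Continuity-correct the chi-square tests (default
#'   FALSE).
#' @return List of data.frames: `demographics`, `cpt`, and (when feature
#'   columns exist) `eeg`.
#' @export
cohort_compare <- function(cohort, chi_correct = FALSE) {
  groups <- unique(as.character(cohort$group))
  if (length(groups) != 2) stop("cohort must contain exactly two groups")
  ga <- if ("PWS" %in% groups) "PWS" else groups[1]
  gb <- setdiff(groups, ga)
  A <- cohort[cohort$group == ga, , drop = FALSE]
  B <- cohort[cohort$group == gb, , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stop("both groups must be non-empty")

  demo <- list()
  if ("age" %in% names(cohort)) {
    demo[[length(demo) + 1L]] <- compare_continuous("age", A$age, B$age)
  }
  if ("sex" %in% names(cohort)) {
    demo[[length(demo) + 1L]] <- compare_binary("sex_male", A$sex == "M",
                                                B$sex == "M", chi_correct)
  }
  if ("intelligence" %in% names(cohort)) {
    demo[[length(demo) + 1L]] <- compare_binary(
      "moderate_severe_id", A$intelligence == 2, B$intelligence == 2, chi_correct)
  }
  if ("bmi" %in% names(cohort)) {
    demo[[length(demo) + 1L]] <- compare_continuous("bmi", A$bmi, B$bmi)
  }
  if ("bmi_z" %in% names(cohort)) {
    demo[[length(demo) + 1L]] <- compare_continuous("bmi_z", A$bmi_z, B$bmi_z)
    demo[[length(demo) + 1L]] <- compare_binary(
      "overweight_obesity", is_overweight_or_obese(A$bmi_z),
      is_overweight_or_obese(B$bmi_z), chi_correct)
  }
  demographics <- do.call(rbind, demo)

  cpt_cols <- paste0("cpt_", cpt_variables())
  cpt_cols <- cpt_cols[cpt_cols %in% names(cohort)]
  cpt <- do.call(rbind, lapply(cpt_cols, function(v) {
    compare_continuous(sub("^cpt_", "", v), A[[v]], B[[v]])
  }))

  feat_cols <- grep("^(tbr|total_power|alpha_ratio)_", names(cohort), value = TRUE)
  eeg <- if (length(feat_cols)) {
    do.call(rbind, lapply(feat_cols, function(v) {
      compare_continuous(v, A[[v]], B[[v]])
    }))
  } else NULL

  out <- list(demographics = demographics, cpt = cpt,
              group_a = ga, group_b = gb)
  if (!is.null(eeg)) out$eeg <- eeg
  out
}
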