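#' Read a BMI reference-norm table
#'
#' The norm table gives, per sex and age band, the reference mean and
#' standard deviation of BMI used to standardize raw BMI into z-scores.
#' Bands are half-open `[age_lo, age_hi)` and must not overlap within a
#' sex.
#'
#' @param path CSV with columns `sex` (`M`/`F`), `age_lo`, `age_hi`,
#'   `mean`, `sd`.
#' @return A data.frame of class `bmi_norm_table`.
#' @export
read_bmi_norms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_lo", "age_hi", "mean", "sd")
  if (!all(need %in% names(tab))) {
    stop("norm table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$sd <= 0)) stop("norm SDs must be positive")
  if (any(tab$age_hi <= tab$age_lo)) stop("age bands must have age_hi > age_lo")
  for (s in unique(tab$sex)) {
    sub <- tab[tab$sex == s, ]
    sub <- sub[order(sub$age_lo), ]
    if (nrow(sub) > 1 && any(sub$age_lo[-1] < sub$age_hi[-nrow(sub)])) {
      stop(sprintf("overlapping age bands for sex %s", s))
    }
  }
  class(tab) <- c("bmi_norm_table", "data.frame")
  tab
}

#' Bundled synthetic BMI norm table
#'
#' A smooth, synthetic age- and sex-specific BMI reference covering ages
#' 5-50 years.  It stands in for a population reference (which is external
#' and not redistributable) so that z-scoring and weight classification are
#' runnable out of the box; substitute a real reference via the
#' `norms` argument of [bmi_zscore()] for substantive use.
#'
#' @return A `bmi_norm_table`.
#' @export
default_bmi_norms <- function() {
  path <- system.file("extdata", "bmi_norms_synthetic.csv", package = "qeegattn")
  if (!nzchar(path)) stop("bundled norm table not found")
  read_bmi_norms(path)
}

#' BMI z-score against an age- and sex-specific reference
#'
#' `z = (bmi - reference mean) / reference SD` for the norm band matching
#' the participant's sex and age.  Vectorized over participants.
#'
#' @param bmi Body-mass index, kg/m^2.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param norms A `bmi_norm_table` (default: the bundled synthetic table).
#' @return Numeric z-score(s), in reference SD units.
#' @export
bmi_zscore <- function(bmi, age, sex, norms = default_bmi_norms()) {
  n <- max(length(bmi), length(age), length(sex))
  bmi <- rep_len(as.numeric(bmi), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  vapply(seq_len(n), function(i) {
    hit <- norms$sex == sex[i] & norms$age_lo <= age[i] & age[i] < norms$age_hi
    if (!any(hit)) {
      stop(sprintf("no norm band for sex %s, age %g", sex[i], age[i]))
    }
    row <- norms[which(hit)[1], ]
    (bmi[i] - row$mean) / row$sd
  }, numeric(1))
}

#' Weight classification from a BMI z-score
#'
#' Overweight is a BMI z-score strictly above 1 and obesity strictly above
#' 2; at most one class applies (obese supersedes overweight).
#'
#' @param z BMI z-score(s).
#' @return Factor with levels `normal`, `overweight`, `obese`.
#' @export
classify_weight <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  factor(ifelse(z > 2, "obese", ifelse(z > 1, "overweight", "normal")),
         levels = c("normal", "overweight", "obese"))
}

#' Overweight-or-obese indicator
#' @param z BMI z-score(s).
#' @return Logical: `z > 1`.
#' @export
is_overweight_or_obese <- function(z) z > 1
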