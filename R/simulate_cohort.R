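#' Parameters of the synthetic behavioral cohort generator
#'
#' Defines the study conditions the cohort generator emulates: two groups
#' of `n_per_group` participants with group-specific demographics, nine
#' T-scored attention-performance (CPT) variables, and EEG session pairs
#' with planted alpha suppression.  The defaults reproduce the reference
#' cohort's published margins: patient/control ages 18.5 +- 8.0 vs
#' 19.8 +- 5.8 years, sex splits 4/6 vs 5/5, six deletion / four
#' non-deletion genotypes, seven of ten patients with moderate-to-severe
#' intellectual disability, BMI 25.7 +- 5.9 vs 23.6 +- 3.5, and the nine
#' per-group CPT T-score means/SDs.  Two couplings plant recoverable
#' structure: the commission T-score is a linear function of the
#' participant's measured raw-mode Cz alpha ratio (slope 25.04), and the
#' omission T-score a linear function of the intelligence category
#' (slope 14.41).
#'
#' @param n_per_group Participants per group (default 10).
#' @param age Per-group mean/SD of age in years (truncated to 6-45 so the
#'   BMI norm table always covers the draw).
#' @param sex_male_frac Fraction of males per group (converted to fixed
#'   counts, not drawn binomially, so small cohorts match the reference
#'   margins exactly).
#' @param genotype_del_frac Fraction of deletion genotypes among patients.
#' @param intel_moderate_frac Fraction of patients with intelligence
#'   category 2 (moderate-to-severe); the rest are category 1, controls 0.
#' @param bmi Per-group mean/SD of BMI (kg/m^2), truncated at 13.
#' @param cpt Data.frame of per-variable, per-group T-score means/SDs for
#'   the seven directly drawn variables (commission and omission come from
#'   the couplings).
#' @param commission Coupling `T = intercept + slope * ratio + N(0, sd)`
#'   on the measured raw-mode Cz alpha ratio.
#' @param omission Coupling `T = intercept + slope * intelligence +
#'   N(0, sd)`.
#' @param eeg An [eeg_sim_params()] for the session pairs.  The default
#'   synthesizes only the midline electrodes the analysis consumes; set
#'   `channels = ELECTRODES_1020` for the full montage.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(
    n_per_group = 10,
    age = list(PWS = c(mean = 18.5, sd = 8.0), control = c(mean = 19.8, sd = 5.8)),
    sex_male_frac = list(PWS = 0.4, control = 0.5),
    genotype_del_frac = 0.6,
    intel_moderate_frac = 0.7,
    bmi = list(PWS = c(mean = 25.7, sd = 5.9), control = c(mean = 23.6, sd = 3.5)),
    cpt = data.frame(
      variable = c("detectability", "perseveration", "hrt", "hrt_sd",
                   "variability", "hrt_block_change", "hrt_isi_change"),
      pws_mean = c(67.6, 78.7, 69.1, 75.7, 71.3, 37.5, 61.1),
      pws_sd   = c(11.2,  7.3, 17.1, 18.4, 16.8, 19.3, 15.8),
      control_mean = c(51.4, 48.8, 48.9, 46.3, 46.7, 52.3, 53.0),
      control_sd   = c( 8.6,  3.2,  7.4,  5.8,  5.3,  9.9,  6.0),
      stringsAsFactors = FALSE),
    commission = c(intercept = 43.0, slope = 25.04, sd = 6.0),
    omission = c(intercept = 49.3, slope = 14.41, sd = 5.7),
    eeg = eeg_sim_params(channels = c("Fz", "Cz", "Pz"))) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (any(cpt$pws_sd <= 0) || any(cpt$control_sd <= 0)) stop("CPT SDs must be positive")
  if (commission[["sd"]] < 0 || omission[["sd"]] < 0) stop("coupling SDs must be non-negative")
  structure(
    list(n_per_group = n_per_group, age = age, sex_male_frac = sex_male_frac,
         genotype_del_frac = genotype_del_frac,
         intel_moderate_frac = intel_moderate_frac, bmi = bmi, cpt = cpt,
         commission = commission, omission = omission, eeg = eeg),
    class = "cohort_sim_params"
  )
}

## Normal draw truncated to [lo, hi] by redrawing.
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

## A fixed multiset of n values with round(frac * n) of `yes`, shuffled.
fixed_count_draw <- function(n, frac, yes, no) {
  k <- round(frac * n)
  sample(c(rep(yes, k), rep(no, n - k)))
}

## Sub-seeds derived reproducibly from a master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Simulate a full synthetic cohort
#'
#' Generates the complete study material: a participant table with
#' demographics, BMI z-scores (via the bundled synthetic norm table),
#' and the nine CPT T-scores, plus one resting + attention EEG session
#' pair per participant with a planted group-dependent alpha suppression.
#' The generator runs the spectral pipeline on its own recordings to
#' obtain each participant's measured Cz alpha ratio, then couples the
#' commission T-score to that measured value, so downstream regression
#' recovery is free of attenuation bias.  A manifest records every planted
#' value.
#'
#' @param params A [cohort_sim_params()].
#' @param seed Integer master seed; the same seed yields a bit-identical
#'   cohort, recordings included.
#' @param norms BMI norm table for z-scoring (default: bundled synthetic).
#' @return An object of class `cohort_sim`: list with `cohort` (the
#'   participant data.frame, including measured `tbr_*`, `total_power_*`
#'   and `alpha_ratio_*` feature columns), `recordings` (per participant:
#'   `resting`, `attention`), `manifest` (planted suppressions, coupling
#'   parameters, seeds), and `params`.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), seed = 1,
                            norms = default_bmi_norms()) {
  n <- params$n_per_group
  groups <- c(rep("PWS", n), rep("control", n))
  ids <- c(sprintf("PWS%02d", seq_len(n)), sprintf("CTL%02d", seq_len(n)))
  seeds <- derive_seeds(seed, 2 * n + 1)
  set.seed(seeds[2 * n + 1])   # stream for demographics + T-scores

  age <- numeric(2 * n); bmi <- numeric(2 * n)
  sex <- character(2 * n); genotype <- character(2 * n)
  intelligence <- integer(2 * n)
  for (g in c("PWS", "control")) {
    idx <- which(groups == g)
    age[idx] <- rnorm_trunc(n, params$age[[g]]["mean"], params$age[[g]]["sd"], 6, 45)
    bmi[idx] <- rnorm_trunc(n, params$bmi[[g]]["mean"], params$bmi[[g]]["sd"], 13, 60)
    sex[idx] <- fixed_count_draw(n, params$sex_male_frac[[g]], "M", "F")
    if (g == "PWS") {
      genotype[idx] <- fixed_count_draw(n, params$genotype_del_frac,
                                        "deletion", "non_deletion")
      intelligence[idx] <- fixed_count_draw(n, params$intel_moderate_frac, 2L, 1L)
    } else {
      genotype[idx] <- NA_character_
      intelligence[idx] <- 0L
    }
  }
  bmi_z <- bmi_zscore(bmi, age, sex, norms)

  ## directly drawn CPT variables
  tscores <- matrix(NA_real_, 2 * n, nrow(params$cpt),
                    dimnames = list(NULL, params$cpt$variable))
  for (i in seq_len(nrow(params$cpt))) {
    v <- params$cpt[i, ]
    tscores[groups == "PWS", i] <- stats::rnorm(n, v$pws_mean, v$pws_sd)
    tscores[groups == "control", i] <- stats::rnorm(n, v$control_mean, v$control_sd)
  }
  commission_noise <- stats::rnorm(2 * n, 0, params$commission[["sd"]])
  omission_noise <- stats::rnorm(2 * n, 0, params$omission[["sd"]])

  ## EEG pairs + measured features
  recordings <- vector("list", 2 * n)
  names(recordings) <- ids
  suppression <- numeric(2 * n)
  feat <- list()
  for (i in seq_len(2 * n)) {
    pair <- simulate_participant_pair(groups[i], params$eeg, seed = seeds[i],
                                      participant_id = ids[i])
    recordings[[i]] <- pair[c("resting", "attention")]
    suppression[i] <- pair$suppression
    feat[[i]] <- measure_pair_features(pair$resting, pair$attention)
  }
  feat <- do.call(rbind, feat)

  commission <- params$commission[["intercept"]] +
    params$commission[["slope"]] * feat$alpha_ratio_raw_Cz + commission_noise
  omission <- params$omission[["intercept"]] +
    params$omission[["slope"]] * intelligence + omission_noise

  cohort <- data.frame(
    id = ids, group = groups, age = age, sex = sex, genotype = genotype,
    intelligence = intelligence, bmi = bmi, bmi_z = bmi_z,
    weight_class = classify_weight(bmi_z),
    stringsAsFactors = FALSE
  )
  cohort$cpt_omission <- omission
  cohort$cpt_commission <- commission
  for (v in colnames(tscores)) cohort[[paste0("cpt_", v)]] <- tscores[, v]
  cohort <- cbind(cohort, feat)

  manifest <- list(
    seed = seed, participant_seeds = seeds[seq_len(2 * n)],
    suppression = stats::setNames(suppression, ids),
    commission_coupling = params$commission,
    omission_coupling = params$omission,
    alpha_suppression_ranges = params$eeg$alpha_suppression,
    low_freq_boost = params$eeg$attention_low_freq_boost
  )
  structure(list(cohort = cohort, recordings = recordings,
                 manifest = manifest, params = params),
            class = "cohort_sim")
}

## Run the spectral pipeline on one session pair and return the feature
## row: per-electrode TBR, resting total power, and alpha ratios in both
## modes.  Uses a 60-s epoch and the default Welch settings.
measure_pair_features <- function(resting, attention,
                                  config = spectral_config(),
                                  epoch_duration = 60) {
  er <- select_clean_epoch(resting, duration = epoch_duration)
  ea <- select_clean_epoch(attention, duration = epoch_duration)
  ps_r <- compute_welch_psd(er, config)
  ps_a <- compute_welch_psd(ea, config)
  ns_r <- normalize_spectrum(ps_r)
  ns_a <- normalize_spectrum(ps_a)
  tbr <- theta_beta_ratio(ps_r)
  tot <- band_power(ps_r, config$total_band)
  ar_raw <- alpha_ratio(ps_a, ps_r)
  ar_norm <- alpha_ratio(ns_a, ns_r)
  row <- as.data.frame(c(
    stats::setNames(as.list(tbr), paste0("tbr_", names(tbr))),
    stats::setNames(as.list(tot), paste0("total_power_", names(tot))),
    stats::setNames(as.list(ar_raw), paste0("alpha_ratio_raw_", names(ar_raw))),
    stats::setNames(as.list(ar_norm), paste0("alpha_ratio_norm_", names(ar_norm)))
  ))
  rownames(row) <- NULL
  row
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d + %d participants, seed %d; planted suppression %.2f-%.2f (PWS) / %.2f-%.2f (control)\n",
              x$params$n_per_group, x$params$n_per_group, x$manifest$seed,
              min(x$manifest$suppression[x$cohort$group == "PWS"]),
              max(x$manifest$suppression[x$cohort$group == "PWS"]),
              min(x$manifest$suppression[x$cohort$group == "control"]),
              max(x$manifest$suppression[x$cohort$group == "control"])))
  invisible(x)
}
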