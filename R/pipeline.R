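#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run.  Exactly one input mode is
#' used: `"simulate"` (generate a synthetic cohort under `sim`) or
#' `"edf_dir"` (read a cohort CSV plus one EDF file per
#' participant-session, named `<id>_<session_tag>.edf`).
#'
#' @param mode `"simulate"` or `"edf_dir"`.
#' @param edf_dir Directory of EDF files (edf_dir mode).
#' @param cohort_csv Participant table CSV (edf_dir mode); columns as in
#'   the `cohort` element of [simulate_cohort()].
#' @param spectral A [spectral_config()].
#' @param ratio_mode Alpha-ratio convention: `"normalized"` (default; the
#'   ratio of normalized alpha fractions) or `"raw"` (ratio of absolute
#'   alpha powers).
#' @param electrodes Midline electrodes of interest (default Fz, Cz, Pz).
#' @param ratio_electrode The electrode whose alpha ratio feeds the
#'   correlation and regression analyses (default Cz).
#' @param epoch_duration Analysis epoch length in seconds (default 60).
#' @param artifact_threshold Artifact amplitude threshold in uV (default
#'   100).
#' @param max_artifact_fraction Maximum tolerated artifact fraction.
#' @param chi_correct Continuity-correct chi-square tests (default FALSE).
#' @param t_var_equal Pooled-variance per-frequency t-tests (default TRUE).
#' @param bh Append Benjamini-Hochberg annotation to per-frequency tests.
#' @param p_enter,p_remove Stepwise selection thresholds.
#' @param sim A [cohort_sim_params()] (simulate mode).
#' @param norms_path Optional CSV path of a BMI norm table; default uses
#'   the bundled synthetic table.
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "edf_dir"),
                       edf_dir = NULL, cohort_csv = NULL,
                       spectral = spectral_config(),
                       ratio_mode = c("normalized", "raw"),
                       electrodes = c("Fz", "Cz", "Pz"),
                       ratio_electrode = "Cz",
                       epoch_duration = 60,
                       artifact_threshold = 100,
                       max_artifact_fraction = 0.1,
                       chi_correct = FALSE, t_var_equal = TRUE, bh = FALSE,
                       p_enter = 0.05, p_remove = 0.10,
                       sim = cohort_sim_params(),
                       norms_path = NULL,
                       seed = 1) {
  mode <- match.arg(mode)
  ratio_mode <- match.arg(ratio_mode)
  if (mode == "edf_dir" && (is.null(edf_dir) || is.null(cohort_csv))) {
    stop("edf_dir mode requires edf_dir and cohort_csv")
  }
  if (!ratio_electrode %in% electrodes) {
    stop("ratio_electrode must be one of the electrodes of interest")
  }
  structure(
    list(mode = mode, edf_dir = edf_dir, cohort_csv = cohort_csv,
         spectral = spectral, ratio_mode = ratio_mode,
         electrodes = electrodes, ratio_electrode = ratio_electrode,
         epoch_duration = epoch_duration,
         artifact_threshold = artifact_threshold,
         max_artifact_fraction = max_artifact_fraction,
         chi_correct = chi_correct, t_var_equal = t_var_equal, bh = bh,
         p_enter = p_enter, p_remove = p_remove,
         sim = sim, norms_path = norms_path, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [run_config()] arguments; nested
#' `spectral` and `sim` mappings are forwarded to [spectral_config()] and
#' [cohort_sim_params()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spectral)) y$spectral <- do.call(spectral_config, y$spectral)
  if (!is.null(y$sim)) y$sim <- do.call(cohort_sim_params, y$sim)
  do.call(run_config, y)
}

## Load the cohort + session pairs for either input mode.
load_inputs <- function(config) {
  if (config$mode == "simulate") {
    norms <- if (is.null(config$norms_path)) default_bmi_norms()
             else read_bmi_norms(config$norms_path)
    sim <- simulate_cohort(config$sim, seed = config$seed, norms = norms)
    list(cohort = sim$cohort, recordings = sim$recordings,
         manifest = sim$manifest)
  } else {
    cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    if (!"id" %in% names(cohort)) stop("cohort CSV must have an 'id' column")
    recordings <- lapply(cohort$id, function(id) {
      load_session <- function(tag) {
        p <- file.path(config$edf_dir, sprintf("%s_%s.edf", id, tag))
        if (!file.exists(p)) stop(sprintf("missing EDF for %s session %s: %s",
                                          id, tag, p))
        read_eeg_edf(p, session_tag = tag)
      }
      list(resting = load_session("rest_eyes_closed"),
           attention = load_session("cpt_task"))
    })
    names(recordings) <- cohort$id
    list(cohort = cohort, recordings = recordings, manifest = NULL)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, for every participant: clean-epoch selection on both the
#' eyes-closed resting and attention-task sessions, Welch PSD, 0-50 Hz
#' normalization, theta/beta ratio and attention-to-resting alpha ratio at
#' the electrodes of interest; then the cohort statistics layer:
#' demographic and CPT group comparisons, resting TBR/total-power
#' comparisons, group-mean normalized spectra with per-frequency t-tests,
#' alpha-ratio group comparisons, Spearman correlations of the designated
#' alpha ratio against the nine CPT variables, and stepwise regressions of
#' the commission and omission T-scores on the alpha ratio, group
#' indicator, age, intelligence, and BMI z-score.  Deterministic given
#' (config, seed).
#'
#' @param config A [run_config()].
#' @return An object of class `cohort_result_bundle`; see
#'   [render_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  inputs <- load_inputs(config)
  cohort <- inputs$cohort

  spectra <- list()   # [[id]]$resting / $attention (raw + normalized)
  features <- list()
  for (id in cohort$id) {
    rec <- inputs$recordings[[id]]
    res <- tryCatch({
      r <- subset_channels(rec$resting, config$electrodes)
      a <- subset_channels(rec$attention, config$electrodes)
      er <- select_clean_epoch(r, duration = config$epoch_duration,
                               threshold = config$artifact_threshold,
                               max_fraction = config$max_artifact_fraction,
                               electrodes = config$electrodes)
      ea <- select_clean_epoch(a, duration = config$epoch_duration,
                               threshold = config$artifact_threshold,
                               max_fraction = config$max_artifact_fraction,
                               electrodes = config$electrodes)
      ps_r <- compute_welch_psd(er, config$spectral)
      ps_a <- compute_welch_psd(ea, config$spectral)
      list(raw_r = ps_r, raw_a = ps_a,
           norm_r = normalize_spectrum(ps_r), norm_a = normalize_spectrum(ps_a))
    }, error = function(e) {
      stop(sprintf("participant %s: %s", id, conditionMessage(e)), call. = FALSE)
    })
    spectra[[id]] <- res
    ar <- if (config$ratio_mode == "raw") alpha_ratio(res$raw_a, res$raw_r)
          else alpha_ratio(res$norm_a, res$norm_r)
    features[[id]] <- data.frame(
      id = id,
      channel = config$electrodes,
      tbr = unname(theta_beta_ratio(res$raw_r)[config$electrodes]),
      total_power = unname(band_power(res$raw_r, config$spectral$total_band)[config$electrodes]),
      alpha_ratio = unname(ar[config$electrodes]),
      stringsAsFactors = FALSE
    )
  }
  features <- do.call(rbind, features)
  rownames(features) <- NULL

  ## wide feature columns joined onto the cohort table for comparisons
  stats_cohort <- cohort[, !grepl("^(tbr|total_power|alpha_ratio)_", names(cohort)),
                         drop = FALSE]
  for (el in config$electrodes) {
    sub <- features[features$channel == el, ]
    sub <- sub[match(stats_cohort$id, sub$id), ]
    stats_cohort[[paste0("tbr_", el)]] <- sub$tbr
    stats_cohort[[paste0("total_power_", el)]] <- sub$total_power
    stats_cohort[[paste0("alpha_ratio_", el)]] <- sub$alpha_ratio
  }

  comparisons <- cohort_compare(stats_cohort, chi_correct = config$chi_correct)
  ga <- comparisons$group_a; gb <- comparisons$group_b
  ids_a <- stats_cohort$id[stats_cohort$group == ga]
  ids_b <- stats_cohort$id[stats_cohort$group == gb]

  ## group-mean normalized spectra + per-frequency t-tests, per session
  session_specs <- list(rest = "norm_r", attention = "norm_a")
  group_spectra <- list(); freq_tests <- list()
  for (sess in names(session_specs)) {
    slot <- session_specs[[sess]]
    sp_a <- lapply(ids_a, function(id) spectra[[id]][[slot]])
    sp_b <- lapply(ids_b, function(id) spectra[[id]][[slot]])
    gs <- per_frequency_spectra(stats::setNames(list(sp_a, sp_b), c(ga, gb)))
    gs$session <- sess
    group_spectra[[sess]] <- gs
    ft <- per_frequency_ttest(sp_a, sp_b, var_equal = config$t_var_equal,
                              bh = config$bh)
    ft$session <- sess
    freq_tests[[sess]] <- ft
  }
  group_spectra <- do.call(rbind, group_spectra)
  freq_tests <- do.call(rbind, freq_tests)
  rownames(group_spectra) <- rownames(freq_tests) <- NULL

  ## Spearman: designated-electrode alpha ratio vs the nine CPT variables
  ratio_col <- paste0("alpha_ratio_", config$ratio_electrode)
  correlations <- do.call(rbind, lapply(cpt_variables(), function(v) {
    col <- paste0("cpt_", v)
    if (!col %in% names(stats_cohort)) return(NULL)
    st <- spearman_test(stats_cohort[[ratio_col]], stats_cohort[[col]])
    data.frame(variable = v, rho = st$rho, p_value = st$p_value, n = st$n,
               stringsAsFactors = FALSE)
  }))

  ## stepwise regressions; group indicator coded control = 0, PWS = 1
  ## (the published tables label this row "genotype"; coding kept as
  ## printed)
  candidates <- data.frame(
    alpha_ratio = stats_cohort[[ratio_col]],
    genotype = as.numeric(stats_cohort$group == ga),
    age = stats_cohort$age,
    intelligence = as.numeric(stats_cohort$intelligence),
    bmi_z = stats_cohort$bmi_z
  )
  reg_commission <- stepwise_regression(stats_cohort$cpt_commission, candidates,
                                        p_enter = config$p_enter,
                                        p_remove = config$p_remove)
  reg_omission <- stepwise_regression(stats_cohort$cpt_omission, candidates,
                                      p_enter = config$p_enter,
                                      p_remove = config$p_remove)

  provenance <- list(
    package_version = as.character(utils::packageVersion("qeegattn")),
    seed = config$seed, mode = config$mode,
    ratio_mode = config$ratio_mode,
    electrodes = config$electrodes,
    ratio_electrode = config$ratio_electrode,
    epoch_duration = config$epoch_duration,
    artifact_threshold = config$artifact_threshold,
    welch = list(window_len = config$spectral$window_len,
                 overlap_frac = config$spectral$overlap_frac,
                 window = config$spectral$window_shape,
                 aggregate = config$spectral$aggregate),
    bands = config$spectral$bands,
    reference_note = "signals analyzed as recorded; no re-referencing applied",
    epoch_rule = "minimal-artifact sliding window (automated stand-in for visual inspection)"
  )

  structure(
    list(cohort = stats_cohort, features = features,
         demographics = comparisons$demographics, cpt = comparisons$cpt,
         eeg_features = comparisons$eeg,
         group_spectra = group_spectra, freq_tests = freq_tests,
         correlations = correlations,
         regression_commission = reg_commission,
         regression_omission = reg_omission,
         manifest = inputs$manifest, provenance = provenance),
    class = "cohort_result_bundle"
  )
}

#' @export
print.cohort_result_bundle <- function(x, ...) {
  cat(sprintf("<cohort_result_bundle> %d participants (%s mode, seed %d)\n",
              nrow(x$cohort), x$provenance$mode, x$provenance$seed))
  cat("blocks: demographics, cpt, eeg_features, group_spectra, freq_tests,\n")
  cat("        correlations, regression_commission, regression_omission\n")
  invisible(x)
}
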