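#' Export a simulated cohort as EDF files plus a cohort CSV
#'
#' Writes one EDF file per participant-session
#' (`<id>_rest_eyes_closed.edf`, `<id>_cpt_task.edf`), the participant
#' table as `cohort.csv`, and the ground-truth manifest as
#' `manifest.json`, making the simulated study readable through the
#' `edf_dir` input mode of [run_pipeline()].
#'
#' @param sim A `cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort_edf <- function(sim, dir) {
  if (!inherits(sim, "cohort_sim")) stop("expected a cohort_sim")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(sim$recordings)) {
    rec <- sim$recordings[[id]]
    write_eeg_edf(rec$resting,
                  file.path(dir, sprintf("%s_rest_eyes_closed.edf", id)))
    write_eeg_edf(rec$attention,
                  file.path(dir, sprintf("%s_cpt_task.edf", id)))
  }
  ## measured feature columns are re-derived from the EDFs downstream;
  ## keep only the drawn participant-level variables in the CSV
  keep <- !grepl("^(tbr|total_power|alpha_ratio)_", names(sim$cohort))
  utils::write.csv(sim$cohort[, keep, drop = FALSE],
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
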