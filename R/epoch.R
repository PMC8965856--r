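#' Select the cleanest contiguous analysis epoch
#'
#' Automated stand-in for visual artifact rejection: slides a window of
#' the requested duration over the recording and selects the one with the
#' smallest fraction of artifact samples, where a sample is an artifact
#' when its absolute voltage exceeds `threshold` on any electrode of
#' interest.  Ties break to the earliest window.  Fails when even the best
#' window exceeds `max_fraction`.
#'
#' @param recording An `eeg_recording`.
#' @param duration Epoch length in seconds (default 60).
#' @param threshold Artifact amplitude threshold in uV (default 100).
#' @param max_fraction Maximum tolerated artifact fraction (default 0.1).
#' @param electrodes Channels inspected for artifacts (default: all
#'   channels present among Fz, Cz, Pz, else all channels).
#' @return An object of class `clean_epoch`: list with `recording` (the
#'   selected segment, `t0` set to its start time), `duration`, and
#'   `artifact_fraction`.
#' @export
select_clean_epoch <- function(recording, duration = 60, threshold = 100,
                               max_fraction = 0.1, electrodes = NULL) {
  if (!inherits(recording, "eeg_recording")) stop("expected an eeg_recording")
  n_need <- round(duration * recording$fs)
  n <- n_samples(recording)
  if (n < n_need) {
    stop(sprintf("recording too short: %.1f s available, %.1f s required",
                 n / recording$fs, duration))
  }
  if (is.null(electrodes)) {
    electrodes <- intersect(c("Fz", "Cz", "Pz"), recording$channel_labels)
    if (!length(electrodes)) electrodes <- recording$channel_labels
  }
  check_electrodes(recording, electrodes)
  x <- recording$data[electrodes, , drop = FALSE]
  bad <- as.numeric(colSums(abs(x) > threshold) > 0)
  csum <- c(0, cumsum(bad))
  starts <- seq_len(n - n_need + 1L)
  frac <- (csum[starts + n_need] - csum[starts]) / n_need
  best <- which.min(frac)           # which.min takes the earliest tie
  if (frac[best] > max_fraction) {
    stop(sprintf("no acceptable window: best artifact fraction %.3f exceeds %.3f",
                 frac[best], max_fraction))
  }
  seg <- recording
  seg$data <- recording$data[, best:(best + n_need - 1L), drop = FALSE]
  seg$t0 <- recording$t0 + (best - 1L) / recording$fs
  structure(
    list(recording = seg, duration = duration,
         artifact_fraction = frac[best]),
    class = "clean_epoch"
  )
}

#' @export
print.clean_epoch <- function(x, ...) {
  cat(sprintf("<clean_epoch> %.0f s from t0 = %.2f s, artifact fraction %.3f\n",
              x$duration, x$recording$t0, x$artifact_fraction))
  invisible(x)
}
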