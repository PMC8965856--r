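#' Construct a multichannel EEG recording
#'
#' Container for a multichannel scalp EEG segment: a channels-by-samples
#' voltage matrix in microvolts plus the sampling rate, 10-20 channel
#' labels, and a session tag identifying the condition under which the
#' recording was acquired.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (default 200).
#' @param channel_labels Character vector of 10-20 electrode names, one per
#'   row of `data`.  Must be unique.
#' @param session_tag One of `"rest_eyes_closed"`, `"rest_eyes_open"`,
#'   `"cpt_task"`, `"noise_rest_closed"`, `"noise_rest_open"`,
#'   `"noise_cpt"`.
#' @param participant_id Participant identifier (free text).
#' @param t0 Start offset of this segment within the original recording, in
#'   seconds.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = 200, channel_labels = rownames(data),
                          session_tag = "rest_eyes_closed",
                          participant_id = "unknown", t0 = 0) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(channel_labels)) {
    stop("channel_labels are required (or supply rownames on `data`)")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row required")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  session_tag <- match.arg(session_tag, SESSION_TAGS)
  rownames(data) <- channel_labels
  structure(
    list(participant_id = participant_id,
         session_tag = session_tag,
         fs = fs,
         channel_labels = channel_labels,
         data = data,
         t0 = t0),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
              x$participant_id, x$session_tag, nrow(x$data), ncol(x$data),
              x$fs, ncol(x$data) / x$fs, x$t0))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec An `eeg_recording`.
#' @return `n_samples()`: integer sample count; `duration_s()`: seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

## Error if the recording lacks any of the requested electrodes.
check_electrodes <- function(rec, electrodes) {
  missing <- setdiff(electrodes, rec$channel_labels)
  if (length(missing)) {
    stop(sprintf("missing electrode(s): %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Restrict a recording to a subset of channels
#'
#' @param rec An `eeg_recording`.
#' @param electrodes Channel labels to keep (order preserved as given).
#' @return An `eeg_recording` with only those channels.
#' @export
subset_channels <- function(rec, electrodes) {
  check_electrodes(rec, electrodes)
  out <- rec
  out$data <- rec$data[electrodes, , drop = FALSE]
  out$channel_labels <- electrodes
  out
}
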