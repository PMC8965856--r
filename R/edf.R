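## Minimal EDF (European Data Format) I/O: fixed 256-byte main header,
## 256 bytes per signal, then 1-s data records of little-endian int16
## samples scaled linearly between the physical and digital ranges.
## Covers uniform-rate EEG; EDF+ annotations are not handled.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop(sprintf("EDF field too long: '%s' (max %d)", x, width))
  formatC(x, width = -width)          # left-justified, space-padded
}

#' Write an EEG recording to an EDF file
#'
#' Serializes a recording as standard EDF: 16-bit samples in 1-s data
#' records, physical units microvolts, one signal per channel.  The
#' physical range is the smallest symmetric integer range covering the
#' data, so the quantization step is `2 * phys_max / 65535`.  Start
#' date/time are written as a fixed constant so that repeated runs are
#' byte-identical.  The recording is truncated to a whole number of
#' seconds.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stop("expected an eeg_recording")
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- n_samples(rec) %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(x)
  phys_max <- pmax(1, ceiling(apply(abs(x), 1, max)))
  dig_max <- 32767L; dig_min <- -32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  ## main header (256 bytes)
  wr(edf_pad("0", 8))                                   # version
  wr(edf_pad(rec$participant_id, 80))                   # patient id
  wr(edf_pad(paste("session", rec$session_tag), 80))    # recording id
  wr(edf_pad("01.01.00", 8))                            # fixed start date
  wr(edf_pad("00.00.00", 8))                            # fixed start time
  wr(edf_pad(256L * (ns + 1L), 8))                      # header bytes
  wr(edf_pad("", 44))                                   # reserved
  wr(edf_pad(n_rec, 8))                                 # number of records
  wr(edf_pad("1", 8))                                   # record duration (s)
  wr(edf_pad(ns, 4))                                    # number of signals
  ## signal headers (256 bytes each, field-major)
  for (lab in rec$channel_labels) wr(edf_pad(paste("EEG", lab), 16))
  for (i in seq_len(ns)) wr(edf_pad("AgAgCl electrode", 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (i in seq_len(ns)) wr(edf_pad(-phys_max[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(phys_max[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_min, 8))
  for (i in seq_len(ns)) wr(edf_pad(dig_max, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))            # prefiltering
  for (i in seq_len(ns)) wr(edf_pad(fs, 8))             # samples per record
  for (i in seq_len(ns)) wr(edf_pad("", 32))            # reserved
  ## data records: per record, per signal, fs int16 samples
  scale <- (dig_max - dig_min) / (2 * phys_max)
  dig <- round(sweep(x, 1, scale, "*"))
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EEG recording from an EDF file
#'
#' Parses a uniform-rate EDF file into an `eeg_recording` in microvolts.
#' Channel labels are normalized by stripping a leading `"EEG "` prefix
#' and surrounding whitespace.  Files whose signals disagree in sampling
#' rate, or whose scaling fields are degenerate, are rejected with the
#' offending header values in the message.
#'
#' @param path EDF file path.
#' @param session_tag Session tag to stamp on the recording; when `NULL`
#'   (default) it is recovered from the recording-id header field if
#'   possible, else `rest_eyes_closed`.
#' @return An `eeg_recording`.
#' @export
read_eeg_edf <- function(path, session_tag = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  recording_id <- rd(80)
  rd(8); rd(8)                                          # date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1 || is.na(rec_dur) || rec_dur <= 0) {
    stop(sprintf("unreadable EDF header: version='%s' signals='%s' records='%s' duration='%s'",
                 version, ns, n_rec, rec_dur))
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                         # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)                         # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)                         # reserved
  if (any(is.na(phys_min + phys_max + dig_min + dig_max)) ||
      any(phys_max <= phys_min) || any(dig_max <= dig_min)) {
    stop(sprintf("ambiguous EDF scaling: phys [%s; %s], dig [%s; %s]",
                 paste(phys_min, collapse = ","), paste(phys_max, collapse = ","),
                 paste(dig_min, collapse = ","), paste(dig_max, collapse = ",")))
  }
  if (length(unique(spr)) != 1) {
    stop(sprintf("non-uniform sampling: samples per record = %s",
                 paste(spr, collapse = ",")))
  }
  fs <- spr[1] / rec_dur
  seek(con, header_bytes)
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  if (length(raw) < n_rec * sum(spr)) stop("truncated EDF data section")
  data <- matrix(0, ns, n_rec * spr[1])
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    block <- raw[((r - 1L) * per_rec + 1L):(r * per_rec)]
    block <- matrix(block, nrow = spr[1])               # samples x signals
    data[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- data * gain + (phys_min - dig_min * gain)
  labels <- sub("^EEG[ _]?", "", labels)
  if (is.null(session_tag)) {
    m <- regmatches(recording_id, regexpr(paste(SESSION_TAGS, collapse = "|"),
                                          recording_id))
    session_tag <- if (length(m)) m else "rest_eyes_closed"
  }
  eeg_recording(data, fs = fs, channel_labels = labels,
                session_tag = session_tag, participant_id = patient)
}
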