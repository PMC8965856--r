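#' Welch power spectral density of an EEG epoch
#'
#' Estimates the one-sided power spectrum of every channel by averaging
#' modified periodograms of overlapping tapered blocks.  Each block is
#' mean-subtracted, Hann-tapered, and scaled by the taper's power
#' (`sum(w^2)`) so that the per-bin powers of a demeaned signal sum to its
#' variance (Parseval contract).  Non-DC, non-Nyquist bins are doubled
#' (one-sided folding).  With 1-s blocks at 1-Hz bins, per-bin power and
#' power density coincide numerically.
#'
#' @param epoch A `clean_epoch` (see [select_clean_epoch()]) or an
#'   `eeg_recording` used directly as the analysis epoch.
#' @param config A [spectral_config()].
#'
#' @return An object of class `power_spectrum`: list with `channel_labels`,
#'   `freqs` (integer-valued Hz bins 0..fs/2), `power` (channels x bins
#'   matrix, uV^2 per bin), `n_segments`, and `config`.
#' @export
compute_welch_psd <- function(epoch, config = spectral_config()) {
  rec <- if (inherits(epoch, "clean_epoch")) epoch$recording else epoch
  if (!inherits(rec, "eeg_recording")) {
    stop("epoch must be a clean_epoch or eeg_recording")
  }
  x <- rec$data
  if (!all(is.finite(x))) stop("invalid signal: non-finite samples")
  fs <- rec$fs
  L <- fs * config$window_len
  if (abs(L - round(L)) > 1e-9) stop("fs * window_len must be an integer")
  L <- as.integer(round(L))
  n <- ncol(x)
  if (n < L) stop("epoch too short: need at least one full window")
  step <- as.integer(round(L * (1 - config$overlap_frac)))
  if (step < 1) stop("overlap too large: step below one sample")
  n_seg <- (n - L) %/% step + 1L
  w <- hann_window(L)
  U <- sum(w^2)
  nb <- L %/% 2L + 1L
  starts <- (seq_len(n_seg) - 1L) * step
  seg_idx <- outer(seq_len(L), starts, "+")   # L x n_seg sample indices
  acc <- matrix(0, nrow(x), nb)
  for (ch in seq_len(nrow(x))) {
    segs <- matrix(x[ch, seg_idx], nrow = L)          # L x n_seg
    segs <- sweep(segs, 2, colMeans(segs), "-")       # demean each block
    segs <- segs * w
    X <- stats::mvfft(segs)
    p <- Mod(X[seq_len(nb), , drop = FALSE])^2 / (L * U)
    if (L %% 2L == 0L) {
      p[2:(nb - 1L), ] <- 2 * p[2:(nb - 1L), ]        # fold, keep DC/Nyquist
    } else if (nb > 1L) {
      p[2:nb, ] <- 2 * p[2:nb, ]
    }
    acc[ch, ] <- if (config$aggregate == "mean") rowMeans(p) else rowSums(p)
  }
  freqs <- (seq_len(nb) - 1L) * config$freq_resolution
  dimnames(acc) <- list(rec$channel_labels, freqs)
  structure(
    list(channel_labels = rec$channel_labels, freqs = freqs, power = acc,
         n_segments = n_seg, config = config,
         participant_id = rec$participant_id, session_tag = rec$session_tag),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d channels, bins %g..%g Hz, %d segments averaged\n",
              length(x$channel_labels), min(x$freqs), max(x$freqs), x$n_segments))
  invisible(x)
}
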