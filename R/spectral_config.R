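#' Spectral analysis configuration
#'
#' Parameters of the Welch estimator and the band definitions.  Defaults
#' follow the clinical qEEG convention used throughout the package: 1-s
#' Hann-windowed blocks with half overlap at 200 Hz, i.e. 1-Hz resolution,
#' and inclusive integer bands theta 4-7 Hz, alpha 8-12 Hz, beta 13-25 Hz.
#' The delta band 0-3 Hz is carried for simulation and per-frequency
#' reporting.  Normalization is always over the 0-50 Hz total.
#'
#' @param window_len Welch block length in seconds (default 1).
#' @param overlap_frac Fractional overlap between consecutive blocks,
#'   in `[0, 1)` (default 0.5).
#' @param window_shape Taper; only `"hann"` is supported.
#' @param freq_resolution Desired bin spacing in Hz; must equal
#'   `1 / window_len` (default 1).
#' @param total_band Inclusive integer range over which spectra are
#'   normalized (default `c(0, 50)`).
#' @param bands Named list of inclusive integer `c(lo, hi)` ranges.
#' @param aggregate How block periodograms are combined: `"mean"` (standard
#'   Welch average, the default) or `"sum"`.  The factor equal to the block
#'   count cancels in every normalized quantity, the theta/beta ratio, and
#'   the alpha ratio, so the choice only affects absolute power.
#'
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(window_len = 1, overlap_frac = 0.5,
                            window_shape = "hann", freq_resolution = 1,
                            total_band = c(0, 50),
                            bands = list(delta = c(0, 3), theta = c(4, 7),
                                         alpha = c(8, 12), beta = c(13, 25)),
                            aggregate = c("mean", "sum")) {
  window_shape <- match.arg(window_shape, "hann")
  aggregate <- match.arg(aggregate)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must be in [0, 1)")
  }
  if (abs(freq_resolution - 1 / window_len) > 1e-12) {
    stop("freq_resolution must equal 1 / window_len")
  }
  if (!length(bands) || is.null(names(bands)) || any(!nzchar(names(bands)))) {
    stop("bands must be a non-empty named list")
  }
  for (b in bands) {
    if (length(b) != 2 || b[1] > b[2]) stop("each band must be c(lo, hi) with lo <= hi")
  }
  structure(
    list(window_len = window_len, overlap_frac = overlap_frac,
         window_shape = window_shape, freq_resolution = freq_resolution,
         total_band = total_band, bands = bands, aggregate = aggregate),
    class = "spectral_config"
  )
}

## Periodic Hann taper of length n.
hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
}

## Resolve a band argument: either a name in config$bands or c(lo, hi).
resolve_band <- function(band, config = NULL) {
  if (is.character(band)) {
    if (is.null(config) || is.null(config$bands[[band]])) {
      stop(sprintf("unknown band '%s'", band))
    }
    band <- config$bands[[band]]
  }
  if (length(band) != 2 || band[1] > band[2]) stop("band must be c(lo, hi)")
  band
}
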