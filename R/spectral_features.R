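## Pull the per-channel value matrix and integer frequency axis out of
## either spectrum flavor.
spectrum_values <- function(spectrum) {
  if (inherits(spectrum, "power_spectrum")) {
    list(values = spectrum$power, freqs = spectrum$freqs,
         labels = spectrum$channel_labels, config = spectrum$config)
  } else if (inherits(spectrum, "normalized_spectrum")) {
    list(values = spectrum$fraction, freqs = spectrum$freqs,
         labels = spectrum$channel_labels, config = spectrum$config)
  } else {
    stop("expected a power_spectrum or normalized_spectrum")
  }
}

#' Band power of a spectrum
#'
#' Sums per-bin values over an inclusive integer frequency range, per
#' channel.  Works on raw (`power_spectrum`) and normalized
#' (`normalized_spectrum`) spectra alike.
#'
#' @param spectrum A `power_spectrum` or `normalized_spectrum`.
#' @param band Either a band name defined in the spectrum's config (e.g.
#'   `"alpha"`) or a numeric `c(lo, hi)` in Hz, inclusive.
#' @return Named numeric vector, one value per channel.
#' @export
band_power <- function(spectrum, band) {
  s <- spectrum_values(spectrum)
  band <- resolve_band(band, s$config)
  if (band[1] < min(s$freqs) || band[2] > max(s$freqs)) {
    stop(sprintf("band [%g, %g] outside spectrum support [%g, %g]",
                 band[1], band[2], min(s$freqs), max(s$freqs)))
  }
  sel <- s$freqs >= band[1] & s$freqs <= band[2]
  stats::setNames(rowSums(s$values[, sel, drop = FALSE]), s$labels)
}

#' Normalize a power spectrum over the 0-50 Hz total
#'
#' Converts per-bin power to the per-bin share of total power over the
#' configured total band (default 0-50 Hz), so each channel's fractions sum
#' to one.  Normalized spectra are scale-invariant: multiplying the input
#' recording by any positive constant leaves them unchanged.
#'
#' @param spectrum A `power_spectrum`.
#' @return An object of class `normalized_spectrum` with `freqs` restricted
#'   to the total band and a `fraction` matrix.
#' @export
normalize_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "power_spectrum")) stop("expected a power_spectrum")
  tb <- spectrum$config$total_band
  sel <- spectrum$freqs >= tb[1] & spectrum$freqs <= tb[2]
  if (max(spectrum$freqs) < tb[2]) {
    stop(sprintf("spectrum support ends at %g Hz, below the total band [%g, %g]",
                 max(spectrum$freqs), tb[1], tb[2]))
  }
  vals <- spectrum$power[, sel, drop = FALSE]
  totals <- rowSums(vals)
  if (any(totals <= 0)) {
    stop(sprintf("degenerate spectrum: zero total power in channel(s) %s",
                 paste(spectrum$channel_labels[totals <= 0], collapse = ", ")))
  }
  frac <- vals / totals
  structure(
    list(channel_labels = spectrum$channel_labels,
         freqs = spectrum$freqs[sel], fraction = frac,
         config = spectrum$config, n_segments = spectrum$n_segments,
         participant_id = spectrum$participant_id,
         session_tag = spectrum$session_tag),
    class = "normalized_spectrum"
  )
}

#' @export
print.normalized_spectrum <- function(x, ...) {
  cat(sprintf("<normalized_spectrum> %d channels, bins %g..%g Hz (fractions sum to 1)\n",
              length(x$channel_labels), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Theta/beta ratio
#'
#' Theta-band power divided by beta-band power, per channel.  The ratio is
#' identical whether computed on the raw or the normalized spectrum (the
#' normalization constant cancels).
#'
#' @param spectrum A `power_spectrum` or `normalized_spectrum`.
#' @return Named numeric vector, one ratio per channel.
#' @export
theta_beta_ratio <- function(spectrum) {
  th <- band_power(spectrum, "theta")
  be <- band_power(spectrum, "beta")
  if (any(be <= 0)) {
    stop(sprintf("undefined TBR: zero beta power in channel(s) %s",
                 paste(names(be)[be <= 0], collapse = ", ")))
  }
  th / be
}

#' Attention-to-resting alpha power ratio
#'
#' The alpha-band (8-12 Hz) power of the attention-task spectrum divided by
#' the alpha-band power of the eyes-closed resting spectrum, per channel.
#' Values below one indicate attention-related alpha suppression; the lower
#' the ratio, the stronger the suppression.  Pass normalized spectra for
#' the normalized-mode ratio (the default convention of [run_pipeline()])
#' or raw spectra for the raw-power mode; with identical total power the
#' two coincide.
#'
#' @param attention Spectrum of the attention-task session.
#' @param resting Spectrum of the eyes-closed resting session.
#' @param band Alpha band; defaults to the config's `"alpha"` range.
#' @return Named numeric vector, one ratio per channel.
#' @export
alpha_ratio <- function(attention, resting, band = "alpha") {
  a <- spectrum_values(attention)
  r <- spectrum_values(resting)
  if (!setequal(a$labels, r$labels)) {
    stop("channel mismatch between attention and resting spectra")
  }
  att <- band_power(attention, band)
  res <- band_power(resting, band)[names(att)]
  if (any(res <= 0)) {
    stop(sprintf("zero resting alpha power in channel(s) %s",
                 paste(names(res)[res <= 0], collapse = ", ")))
  }
  att / res
}

#' Per-channel spectral feature table
#'
#' Band powers, total 0-50 Hz power, and theta/beta ratio of a resting
#' spectrum; when the matching attention spectrum is supplied, the
#' attention-to-resting alpha power ratio is appended.
#'
#' @param resting Spectrum of the resting session (raw or normalized).
#' @param attention Optional spectrum of the attention session (same type).
#' @return A data.frame with one row per channel: `channel`, `theta_power`,
#'   `alpha_power`, `beta_power`, `total_power_0_50`, `tbr`, and
#'   `alpha_ratio` (NA when no attention spectrum given).
#' @export
spectral_features <- function(resting, attention = NULL) {
  s <- spectrum_values(resting)
  tb <- s$config$total_band
  out <- data.frame(
    channel = s$labels,
    theta_power = unname(band_power(resting, "theta")),
    alpha_power = unname(band_power(resting, "alpha")),
    beta_power = unname(band_power(resting, "beta")),
    total_power_0_50 = unname(band_power(resting, tb)),
    tbr = unname(theta_beta_ratio(resting)),
    alpha_ratio = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(attention)) {
    out$alpha_ratio <- unname(alpha_ratio(attention, resting)[s$labels])
  }
  out
}

#' Group-mean normalized spectra
#'
#' Aggregates participants' normalized spectra into per-group, per-session
#' mean and standard-deviation tracks at each frequency bin, the input to
#' the per-frequency group t-test.
#'
#' @param spectra Named list: group name -> list of `normalized_spectrum`
#'   objects (one per participant), all on the same bins and channels.
#' @return A data.frame with columns `group`, `channel`, `freq`, `mean`,
#'   `sd`, `n`.
#' @export
per_frequency_spectra <- function(spectra) {
  if (!length(spectra) || is.null(names(spectra))) {
    stop("spectra must be a named list of groups")
  }
  out <- list()
  for (g in names(spectra)) {
    members <- spectra[[g]]
    if (length(members) < 2) stop(sprintf("group '%s' has fewer than 2 participants", g))
    ref <- spectrum_values(members[[1]])
    for (ch in ref$labels) {
      mat <- vapply(members, function(sp) {
        s <- spectrum_values(sp)
        if (!identical(s$freqs, ref$freqs)) stop("frequency grids differ")
        s$values[ch, ]
      }, numeric(length(ref$freqs)))            # bins x participants
      out[[length(out) + 1L]] <- data.frame(
        group = g, channel = ch, freq = ref$freqs,
        mean = rowMeans(mat), sd = apply(mat, 1, stats::sd),
        n = length(members), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Long-format table of a spectrum
#'
#' @param spectrum A `power_spectrum` or `normalized_spectrum`.
#' @return Tidy data.frame: `participant_id`, `session`, `channel`, `freq`,
#'   `value`.
#' @export
spectrum_table <- function(spectrum) {
  s <- spectrum_values(spectrum)
  data.frame(
    participant_id = spectrum$participant_id %||% NA_character_,
    session = spectrum$session_tag %||% NA_character_,
    channel = rep(s$labels, each = length(s$freqs)),
    freq = rep(s$freqs, times = length(s$labels)),
    value = as.vector(t(s$values)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
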