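#' Parameters of the synthetic EEG generator
#'
#' The generator builds each channel as a sum of a 1/f^beta Gaussian
#' background (spectrally shaped white noise) and four narrow-band
#' stochastic oscillators (band-limited filtered noise, so band power
#' varies naturally across 1-s analysis blocks).  Attention-task sessions
#' remove a fraction `s` of alpha *power* (the alpha amplitude scales by
#' `sqrt(1 - s)`); for the control group they additionally multiply
#' delta- and theta-band power by `attention_low_freq_boost`.  Controls
#' draw `s` uniformly from 0.60-0.70; patients from a wide band centered
#' on 0.30, reflecting the heterogeneous, on-average-weak suppression
#' observed in the patient group.
#'
#' @param fs Sampling rate in Hz (default 200).
#' @param duration Session length in seconds (default 70, so a 60-s
#'   analysis epoch can be selected within it).
#' @param background_exponent Spectral slope beta of the 1/f^beta
#'   background (default 1).
#' @param background_scale Background RMS amplitude in uV (default 4).
#' @param oscillators Data.frame with columns `name`, `center` (Hz),
#'   `bandwidth` (FWHM, Hz), `amplitude` (RMS uV).  Defaults: delta (2,
#'   1.5, 3), theta (6, 2, 3), alpha (10, 2, 6), beta (20, 6, 2); the
#'   bandwidths keep >= 95% of each oscillator's power inside its nominal
#'   band at 1-Hz bins.
#' @param alpha_suppression Named list of `c(lo, hi)` uniform ranges for
#'   the planted alpha power suppression per group.
#' @param attention_low_freq_boost Multiplicative delta+theta power gain in
#'   the control group's attention session (default 1.5).
#' @param artifact_rate High-amplitude transients per minute (default 0);
#'   used to exercise epoch selection.
#' @param artifact_amplitude Peak amplitude of a transient in uV.
#' @param channels Channel labels to synthesize (default the 19-electrode
#'   10-20 montage).
#' @return An object of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(fs = 200, duration = 70,
                           background_exponent = 1, background_scale = 4,
                           oscillators = data.frame(
                             name = c("delta", "theta", "alpha", "beta"),
                             center = c(2, 6, 10, 20),
                             bandwidth = c(1.5, 2, 2, 6),
                             amplitude = c(3, 3, 6, 2),
                             stringsAsFactors = FALSE),
                           alpha_suppression = list(control = c(0.60, 0.70),
                                                    PWS = c(0.05, 0.55)),
                           attention_low_freq_boost = 1.5,
                           artifact_rate = 0, artifact_amplitude = 300,
                           channels = ELECTRODES_1020) {
  if (any(oscillators$amplitude < 0)) stop("oscillator amplitudes must be >= 0")
  for (r in alpha_suppression) {
    if (any(r < 0) || any(r >= 1)) stop("suppression fractions must be in [0, 1)")
  }
  if (duration <= 0 || fs <= 0) stop("fs and duration must be positive")
  structure(
    list(fs = fs, duration = duration,
         background_exponent = background_exponent,
         background_scale = background_scale,
         oscillators = oscillators,
         alpha_suppression = alpha_suppression,
         attention_low_freq_boost = attention_low_freq_boost,
         artifact_rate = artifact_rate,
         artifact_amplitude = artifact_amplitude,
         channels = channels),
    class = "eeg_sim_params"
  )
}

## Real signal with prescribed amplitude response: shape white Gaussian
## noise in the frequency domain with a symmetric gain H(f) and invert.
## x is an n x n_ch matrix of white noise; gain is a function of |f| >= 0.
shape_noise <- function(x, fs, gain) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                # fold to |f|
  H <- gain(f)
  H[1] <- 0                           # no DC
  X <- stats::mvfft(x) * H
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

## Normalize columns to unit RMS (zero columns left untouched).
unit_rms <- function(x) {
  r <- sqrt(colMeans(x^2))
  r[r == 0] <- 1
  sweep(x, 2, r, "/")
}

## Draw the independent signal components of one participant-session
## lineage: list of n x n_ch matrices at unit RMS (background at
## background_scale RMS).  Consumes the current RNG stream.
draw_components <- function(params) {
  n <- round(params$fs * params$duration)
  n_ch <- length(params$channels)
  beta <- params$background_exponent
  bg <- shape_noise(matrix(stats::rnorm(n * n_ch), n, n_ch), params$fs,
                    function(f) ifelse(f < 0.5, 0.5^(-beta / 2), f^(-beta / 2)))
  bg <- unit_rms(bg) * params$background_scale
  osc <- lapply(seq_len(nrow(params$oscillators)), function(i) {
    o <- params$oscillators[i, ]
    sigma <- o$bandwidth / (2 * sqrt(2 * log(2)))   # FWHM -> Gaussian SD
    z <- shape_noise(matrix(stats::rnorm(n * n_ch), n, n_ch), params$fs,
                     function(f) exp(-(f - o$center)^2 / (2 * sigma^2)))
    unit_rms(z)
  })
  names(osc) <- params$oscillators$name
  list(background = bg, oscillators = osc, n = n, n_ch = n_ch)
}

## Compose a recording from drawn components and per-oscillator amplitude
## multipliers; optionally superimpose artifact transients.
compose_session <- function(comp, params, participant_id, session_tag,
                            osc_gain = NULL) {
  amp <- stats::setNames(params$oscillators$amplitude, params$oscillators$name)
  if (!is.null(osc_gain)) {
    amp[names(osc_gain)] <- amp[names(osc_gain)] * unlist(osc_gain)
  }
  sig <- comp$background
  for (nm in names(comp$oscillators)) {
    sig <- sig + comp$oscillators[[nm]] * amp[[nm]]
  }
  if (params$artifact_rate > 0) {
    n_art <- stats::rpois(1, params$artifact_rate * params$duration / 60)
    if (n_art > 0) {
      width <- round(0.3 * params$fs)
      pulse <- params$artifact_amplitude *
        exp(-((seq_len(width) - width / 2)^2) / (2 * (width / 6)^2))
      for (k in seq_len(n_art)) {
        at <- sample.int(comp$n - width, 1)
        sig[at:(at + width - 1), ] <- sig[at:(at + width - 1), ] + pulse
      }
    }
  }
  eeg_recording(t(sig), fs = params$fs, channel_labels = params$channels,
                session_tag = session_tag, participant_id = participant_id)
}

## Uniform draw of the planted suppression for a group.
draw_suppression <- function(group, params) {
  rng <- params$alpha_suppression[[group]]
  if (is.null(rng)) stop(sprintf("no suppression range for group '%s'", group))
  stats::runif(1, rng[1], rng[2])
}

#' Simulate one EEG session
#'
#' Generates a single synthetic recording for a participant of the given
#' group.  Resting sessions contain the full oscillator set over the 1/f
#' background; attention-task sessions (`cpt_task`, `noise_cpt`) apply the
#' planted alpha power suppression (drawn from the group's range unless
#' `suppression` is given) and, for controls, the low-frequency boost.
#'
#' @param group `"PWS"` or `"control"` (must key into
#'   `params$alpha_suppression`).
#' @param session_tag Session condition tag (see [eeg_recording()]).
#' @param params An [eeg_sim_params()].
#' @param seed Integer seed; the same seed yields a bit-identical
#'   recording.
#' @param suppression Optional fixed alpha power suppression in `[0, 1)`,
#'   overriding the group draw.
#' @param participant_id Identifier stamped on the recording.
#' @return An `eeg_recording` with an attribute `planted` (list with
#'   `suppression`, `low_freq_boost`).
#' @export
simulate_eeg_session <- function(group, session_tag, params = eeg_sim_params(),
                                 seed = 1, suppression = NULL,
                                 participant_id = paste0(group, "-sim")) {
  set.seed(seed)
  comp <- draw_components(params)
  attention <- session_tag %in% c("cpt_task", "noise_cpt")
  s <- 0
  boost <- 1
  if (attention) {
    s <- if (is.null(suppression)) draw_suppression(group, params) else suppression
    if (group == "control") boost <- params$attention_low_freq_boost
  }
  gain <- list(alpha = sqrt(1 - s), delta = sqrt(boost), theta = sqrt(boost))
  rec <- compose_session(comp, params, participant_id, session_tag,
                         osc_gain = if (attention) gain else NULL)
  attr(rec, "planted") <- list(suppression = if (attention) s else NA_real_,
                               low_freq_boost = if (attention) boost else 1)
  rec
}

#' Simulate a resting + attention session pair
#'
#' Draws one set of background and oscillator realizations and composes
#' both sessions from it, so that the two sessions share phases and differ
#' only by the planted attention modifications (alpha amplitude scaled by
#' `sqrt(1 - s)`; delta/theta boost for controls).  This makes the planted
#' suppression recoverable with minimal sampling noise: in raw mode, the
#' attention/resting alpha oscillator power ratio is exactly `1 - s` per
#' realization.
#'
#' @inheritParams simulate_eeg_session
#' @return List with `resting` and `attention` (`eeg_recording`s),
#'   `suppression` (the drawn or supplied `s`), and `low_freq_boost`.
#' @export
simulate_participant_pair <- function(group, params = eeg_sim_params(),
                                      seed = 1, suppression = NULL,
                                      participant_id = paste0(group, "-sim")) {
  set.seed(seed)
  s <- if (is.null(suppression)) draw_suppression(group, params) else suppression
  boost <- if (group == "control") params$attention_low_freq_boost else 1
  comp <- draw_components(params)
  resting <- compose_session(comp, params, participant_id, "rest_eyes_closed")
  attention <- compose_session(
    comp, params, participant_id, "cpt_task",
    osc_gain = list(alpha = sqrt(1 - s), delta = sqrt(boost),
                    theta = sqrt(boost)))
  attr(resting, "planted") <- list(suppression = NA_real_, low_freq_boost = 1)
  attr(attention, "planted") <- list(suppression = s, low_freq_boost = boost)
  list(resting = resting, attention = attention,
       suppression = s, low_freq_boost = boost)
}
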