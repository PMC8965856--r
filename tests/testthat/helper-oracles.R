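# Independent oracles and small constructors shared across tests.

# Brute-force Welch estimate for one channel: explicit loop over blocks,
# naive DFT (no FFT), Hann taper, taper-power compensation, one-sided
# folding.  Deliberately mirrors the *definition*, not the implementation.
naive_welch_psd <- function(x, fs, window_len = 1, overlap_frac = 0.5,
                            aggregate = "mean") {
  L <- round(fs * window_len)
  step <- round(L * (1 - overlap_frac))
  n_seg <- (length(x) - L) %/% step + 1
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  U <- sum(w^2)
  nb <- L %/% 2 + 1
  acc <- numeric(nb)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * step + 1):((s - 1) * step + L)]
    seg <- (seg - mean(seg)) * w
    for (k in 0:(nb - 1)) {
      Xk <- sum(seg * exp(-2i * pi * k * (0:(L - 1)) / L))
      p <- Mod(Xk)^2 / (L * U)
      if (k > 0 && !(L %% 2 == 0 && k == nb - 1)) p <- 2 * p
      acc[k + 1] <- acc[k + 1] + p
    }
  }
  if (aggregate == "mean") acc / n_seg else acc
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (tie-free data only).
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx_a) {
    ra <- rank(pooled)[idx_a]
    sum(ra) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Hand-built power spectrum on integer bins 0..100 Hz from a per-bin
# value matrix (channels x 101), bypassing the estimator.
make_spectrum <- function(values, labels = paste0("ch", seq_len(nrow(values))),
                          config = spectral_config()) {
  values <- as.matrix(values)
  freqs <- 0:(ncol(values) - 1)
  dimnames(values) <- list(labels, freqs)
  structure(
    list(channel_labels = labels, freqs = freqs, power = values,
         n_segments = 1L, config = config,
         participant_id = "fixture", session_tag = "rest_eyes_closed"),
    class = "power_spectrum"
  )
}

# Sine-wave recording helper.
sine_recording <- function(freq, fs = 200, duration = 60, amplitude = 1,
                           channels = "Cz") {
  t <- (0:(duration * fs - 1)) / fs
  data <- matrix(rep(amplitude * sin(2 * pi * freq * t), length(channels)),
                 nrow = length(channels), byrow = TRUE)
  eeg_recording(data, fs = fs, channel_labels = channels)
}

# Small single-channel generator params used to keep simulations cheap.
cz_sim_params <- function(...) eeg_sim_params(channels = "Cz", ...)

# Measured raw-mode Cz alpha ratio of a simulated session pair.
measure_raw_cz_ratio <- function(pair) {
  er <- select_clean_epoch(pair$resting)
  ea <- select_clean_epoch(pair$attention)
  unname(alpha_ratio(compute_welch_psd(ea), compute_welch_psd(er))["Cz"])
}
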