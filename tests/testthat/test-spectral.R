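test_that("Welch estimator: segment count, zero signal, and error contract", {
  rec <- eeg_recording(matrix(0, 3, 60 * 200), fs = 200,
                       channel_labels = c("Fz", "Cz", "Pz"))
  ps <- compute_welch_psd(rec)
  expect_identical(ps$n_segments, 119L)
  expect_true(all(ps$power == 0))
  expect_equal(ps$freqs, 0:100)

  short <- eeg_recording(matrix(0, 1, 100), fs = 200, channel_labels = "Cz")
  expect_error(compute_welch_psd(short), "epoch too short")
  bad <- eeg_recording(matrix(c(1, NA), 1, 400), fs = 200, channel_labels = "Cz")
  expect_error(compute_welch_psd(bad), "invalid signal")
})

test_that("pure 10 Hz sinusoid: power concentrates in 9-11 Hz and total is A^2/2", {
  ps <- compute_welch_psd(sine_recording(10))
  total <- sum(ps$power)
  expect_gt(sum(ps$power[1, 10:12]) / total, 0.99)   # bins 9, 10, 11
  expect_lt(abs(total - 0.5), 0.01)                  # variance of unit sine
})

test_that("white-noise total power satisfies Parseval against sample variance", {
  set.seed(42)
  for (i in 1:3) {
    x <- rnorm(60 * 200)
    ps <- compute_welch_psd(eeg_recording(rbind(x), fs = 200, channel_labels = "Cz"))
    expect_gt(sum(ps$power) / var(x), 0.95)
    expect_lt(sum(ps$power) / var(x), 1.05)
  }
})

test_that("Welch matches the naive-DFT segment-averaging oracle", {
  set.seed(7)
  fs <- 40
  for (i in 1:4) {
    x <- rnorm(2 * fs) + sin(2 * pi * 7 * (0:(2 * fs - 1)) / fs)
    rec <- eeg_recording(rbind(x), fs = fs, channel_labels = "Cz",
                         session_tag = "rest_eyes_closed")
    for (agg in c("mean", "sum")) {
      cfg <- spectral_config(total_band = c(0, fs / 2), aggregate = agg)
      got <- compute_welch_psd(rec, cfg)$power[1, ]
      want <- naive_welch_psd(x, fs, aggregate = agg)
      expect_lt(max(abs(got - want)) / max(want), 1e-6)
    }
  }
})

test_that("band_power sums inclusive integer bins", {
  flat <- make_spectrum(matrix(1, 1, 101))
  expect_equal(unname(band_power(flat, "theta")), 4)
  expect_equal(unname(band_power(flat, "alpha")), 5)
  expect_equal(unname(band_power(flat, "beta")), 13)
  expect_equal(unname(band_power(flat, c(0, 50))), 51)

  spike <- make_spectrum(matrix(c(rep(0, 10), 7, rep(0, 90)), 1))  # all at 10 Hz
  expect_equal(unname(band_power(spike, "alpha")), 7)
  expect_equal(unname(band_power(spike, "theta")), 0)
  expect_equal(unname(band_power(spike, "beta")), 0)

  set.seed(1)
  v <- matrix(runif(101), 1)
  expect_equal(band_power(make_spectrum(3.7 * v), "alpha"),
               3.7 * band_power(make_spectrum(v), "alpha"))
  expect_error(band_power(flat, c(90, 120)), "outside")
})

test_that("band definitions tile 0-50 Hz without overlap", {
  cfg <- spectral_config()
  bands <- c(cfg$bands, list(high = c(26, 50)))
  bins <- unname(unlist(lapply(bands, function(b) b[1]:b[2])))
  expect_equal(sort(bins), 0:50)              # disjoint and exhaustive
})

test_that("normalize_spectrum yields per-channel fractions summing to one", {
  uni <- normalize_spectrum(make_spectrum(matrix(1, 2, 101)))
  expect_equal(as.vector(uni$fraction), rep(1 / 51, 2 * 51))

  set.seed(3)
  ns <- normalize_spectrum(make_spectrum(matrix(rexp(3 * 101), 3)))
  expect_true(all(abs(rowSums(ns$fraction) - 1) < 1e-9))
  expect_true(all(ns$fraction >= 0 & ns$fraction <= 1))

  v <- matrix(rexp(101), 1)
  expect_equal(normalize_spectrum(make_spectrum(5.1 * v))$fraction,
               normalize_spectrum(make_spectrum(v))$fraction)
  expect_error(normalize_spectrum(make_spectrum(matrix(0, 1, 101))),
               "degenerate spectrum")
})

test_that("theta/beta ratio: arithmetic, normalization invariance, errors", {
  v <- matrix(0, 1, 101)
  v[1, 5:8] <- 3            # theta bins 4-7 -> 12
  v[1, 14:17] <- 1          # four beta bins -> 4
  expect_equal(unname(theta_beta_ratio(make_spectrum(v))), 3.0)

  flat <- make_spectrum(matrix(1, 1, 101))
  expect_equal(unname(theta_beta_ratio(flat)), 4 / 13)

  set.seed(11)
  sp <- make_spectrum(matrix(rexp(2 * 101), 2), labels = c("Fz", "Cz"))
  expect_lt(max(abs(theta_beta_ratio(sp) - theta_beta_ratio(normalize_spectrum(sp)))),
            1e-12)

  nobeta <- make_spectrum(matrix(c(rep(1, 13), rep(0, 88)), 1))
  expect_error(theta_beta_ratio(nobeta), "undefined TBR")
})

test_that("alpha ratio: identity, planted scaling, channel contract", {
  set.seed(5)
  v <- matrix(rexp(2 * 101), 2)
  sp <- make_spectrum(v, labels = c("Fz", "Cz"))
  expect_equal(unname(alpha_ratio(sp, sp)), c(1, 1))

  att <- v
  att[, 9:13] <- att[, 9:13] * 0.35          # alpha bins 8-12
  expect_equal(unname(alpha_ratio(make_spectrum(att, labels = c("Fz", "Cz")), sp)),
               c(0.35, 0.35))

  other <- make_spectrum(v, labels = c("Fz", "Pz"))
  expect_error(alpha_ratio(other, sp), "channel mismatch")
  dead <- v; dead[1, 9:13] <- 0
  expect_error(alpha_ratio(sp, make_spectrum(dead, labels = c("Fz", "Cz"))),
               "zero resting alpha")
})

test_that("normalized spectra, TBR and alpha ratio are scale invariant", {
  set.seed(9)
  x <- matrix(rnorm(2 * 60 * 200), 2)
  r1 <- eeg_recording(x, fs = 200, channel_labels = c("Fz", "Cz"))
  r2 <- eeg_recording(137.5 * x, fs = 200, channel_labels = c("Fz", "Cz"))
  p1 <- compute_welch_psd(r1); p2 <- compute_welch_psd(r2)
  expect_lt(max(abs(normalize_spectrum(p1)$fraction - normalize_spectrum(p2)$fraction)),
            1e-9)
  expect_lt(max(abs(theta_beta_ratio(p1) - theta_beta_ratio(p2))), 1e-9)
  y <- matrix(rnorm(2 * 60 * 200), 2)       # "attention" signal
  a1 <- compute_welch_psd(eeg_recording(y, fs = 200,
                                        channel_labels = c("Fz", "Cz")))
  a2 <- compute_welch_psd(eeg_recording(137.5 * y, fs = 200,
                                        channel_labels = c("Fz", "Cz")))
  expect_lt(max(abs(alpha_ratio(a1, p1) - alpha_ratio(a2, p2))), 1e-9)
  expect_lt(max(abs(alpha_ratio(normalize_spectrum(a1), normalize_spectrum(p1)) -
                    alpha_ratio(normalize_spectrum(a2), normalize_spectrum(p2)))),
            1e-9)
})

test_that("spectral_features assembles the per-channel table", {
  set.seed(13)
  rest <- make_spectrum(matrix(rexp(2 * 101) + 0.1, 2), labels = c("Fz", "Cz"))
  att <- make_spectrum(matrix(rexp(2 * 101) + 0.1, 2), labels = c("Fz", "Cz"))
  ft <- spectral_features(rest, att)
  expect_identical(ft$channel, c("Fz", "Cz"))
  expect_equal(ft$tbr, unname(theta_beta_ratio(rest)))
  expect_equal(ft$alpha_ratio, unname(alpha_ratio(att, rest)))
  expect_true(all(is.na(spectral_features(rest)$alpha_ratio)))
})

test_that("group-mean spectra: zero dispersion for clones, convexity, order invariance", {
  set.seed(17)
  base <- normalize_spectrum(make_spectrum(matrix(rexp(101) + 0.1, 1), labels = "Cz"))
  other <- normalize_spectrum(make_spectrum(matrix(rexp(101) + 0.1, 1), labels = "Cz"))
  g <- per_frequency_spectra(list(A = list(base, base), B = list(base, other)))
  expect_true(all(g$sd[g$group == "A"] == 0))
  for (grp in c("A", "B")) {
    expect_equal(sum(g$mean[g$group == grp]), 1)        # convex combination
  }
  g2 <- per_frequency_spectra(list(A = list(base, base), B = list(other, base)))
  expect_equal(g$mean, g2$mean)
  expect_error(per_frequency_spectra(list(A = list(base))), "fewer than 2")
})
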