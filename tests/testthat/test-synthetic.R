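test_that("simulation is bit-identical under a fixed seed at every level", {
  p <- cz_sim_params()
  r1 <- simulate_eeg_session("control", "rest_eyes_closed", p, seed = 5)
  r2 <- simulate_eeg_session("control", "rest_eyes_closed", p, seed = 5)
  expect_identical(r1$data, r2$data)
  pr1 <- simulate_participant_pair("PWS", p, seed = 5)
  pr2 <- simulate_participant_pair("PWS", p, seed = 5)
  expect_identical(pr1$attention$data, pr2$attention$data)
  expect_identical(pr1$suppression, pr2$suppression)
  s1 <- simulate_cohort(cohort_sim_params(n_per_group = 2), seed = 5)
  s2 <- simulate_cohort(cohort_sim_params(n_per_group = 2), seed = 5)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$recordings[[1]]$resting$data, s2$recordings[[1]]$resting$data)
})

test_that("with the alpha oscillator silenced, the alpha band carries only background leakage", {
  p <- cz_sim_params()
  p$oscillators$amplitude[p$oscillators$name == "alpha"] <- 0
  fr <- vapply(1:10, function(s) {
    rec <- simulate_eeg_session("control", "rest_eyes_closed", p, seed = s)
    ns <- normalize_spectrum(compute_welch_psd(select_clean_epoch(rec)))
    unname(band_power(ns, "alpha")["Cz"])
  }, numeric(1))
  expect_lt(mean(fr), 0.05)
  expect_true(all(fr < 0.07))
})

test_that("eyes-closed resting simulation makes alpha the modal band at Cz", {
  modal <- vapply(1:20, function(s) {
    rec <- simulate_eeg_session("control", "rest_eyes_closed", cz_sim_params(),
                                seed = s)
    ns <- normalize_spectrum(compute_welch_psd(select_clean_epoch(rec)))
    a <- band_power(ns, "alpha"); th <- band_power(ns, "theta")
    be <- band_power(ns, "beta")
    unname(a["Cz"] > th["Cz"] && a["Cz"] > be["Cz"])
  }, logical(1))
  expect_true(all(modal))
})

test_that("background-only spectrum follows the configured 1/f slope", {
  p <- cz_sim_params()
  p$oscillators$amplitude[] <- 0
  slopes <- vapply(1:5, function(s) {
    rec <- simulate_eeg_session("control", "rest_eyes_closed", p, seed = s)
    ps <- compute_welch_psd(select_clean_epoch(rec))
    sel <- ps$freqs >= 2 & ps$freqs <= 40
    unname(coef(lm(log(ps$power[1, sel]) ~ log(ps$freqs[sel])))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - (-1)) < 0.3))
})

test_that("planted suppression is recovered by the raw-mode alpha ratio", {
  p <- cz_sim_params()
  mean_ratio <- function(s, n = 20) {
    mean(vapply(seq_len(n), function(seed) {
      measure_raw_cz_ratio(simulate_participant_pair("control", p, seed = seed,
                                                     suppression = s))
    }, numeric(1)))
  }
  expect_lt(abs(mean_ratio(0) - 1), 0.1)       # no-effect case
  ## monotone decrease in planted suppression (seed-averaged means)
  ms <- vapply(c(0, 0.3, 0.65, 0.9), mean_ratio, numeric(1), n = 10)
  expect_true(all(diff(ms) < 0))
})

test_that("attention boost raises low-frequency power only for controls", {
  p <- cz_sim_params()
  lowfreq <- function(group, seed) {
    pr <- simulate_participant_pair(group, p, seed = seed, suppression = 0.4)
    pa <- compute_welch_psd(select_clean_epoch(pr$attention))
    pr_ <- compute_welch_psd(select_clean_epoch(pr$resting))
    unname((band_power(pa, "delta") + band_power(pa, "theta")) /
           (band_power(pr_, "delta") + band_power(pr_, "theta")))
  }
  ctl <- vapply(1:5, function(s) lowfreq("control", s), numeric(1))
  pws <- vapply(1:5, function(s) lowfreq("PWS", s), numeric(1))
  expect_true(all(ctl > 1.2))                  # planted x1.5 power gain
  expect_true(all(abs(pws - 1) < 0.1))         # no change in patients
})

test_that("group difference planted only in the alpha band drives the per-frequency t-test", {
  ## raw attention spectra: with the low-frequency boost disabled, the two
  ## groups differ in distribution only at the suppressed alpha bins
  p <- cz_sim_params(attention_low_freq_boost = 1)
  hits <- vapply(1:15, function(rep) {
    seeds <- 1000 * rep + seq_len(12)
    sp <- lapply(seq_len(12), function(i) {
      grp <- if (i <= 6) "control" else "PWS"
      pr <- simulate_participant_pair(grp, p, seed = seeds[i])
      compute_welch_psd(select_clean_epoch(pr$attention))
    })
    ft <- per_frequency_ttest(sp[1:6], sp[7:12])
    ft$freq[which.min(ft$p_value)] %in% 8:12
  }, logical(1))
  expect_gte(sum(hits), 14)
})

test_that("cohort generator reproduces the configured T-score distributions", {
  sim <- simulate_cohort(cohort_sim_params(n_per_group = 200), seed = 11)
  co <- sim$cohort
  expect_lt(abs(mean(co$cpt_omission[co$group == "PWS"]) - 74.4), 3)
  expect_lt(abs(mean(co$cpt_perseveration[co$group == "control"]) - 48.8), 1)
  ## fixed-count margins scale with n
  expect_equal(sum(co$sex[co$group == "PWS"] == "M"), 80)
  expect_equal(sum(co$intelligence[co$group == "PWS"] == 2), 140)
  expect_true(all(co$intelligence[co$group == "control"] == 0))
  expect_true(all(co$age > 5))
})

test_that("noise-free coupling makes commission a monotone function of the alpha ratio", {
  p <- cohort_sim_params()
  p$commission[["sd"]] <- 0
  sim <- simulate_cohort(p, seed = 5)
  expect_equal(cor(rank(sim$cohort$alpha_ratio_raw_Cz),
                   rank(sim$cohort$cpt_commission)), 1)
})

test_that("manifest round-trips every planted value", {
  sim <- simulate_cohort(cohort_sim_params(n_per_group = 3), seed = 9)
  expect_identical(names(sim$manifest$suppression), sim$cohort$id)
  for (id in sim$cohort$id) {
    planted <- attr(sim$recordings[[id]]$attention, "planted")
    expect_identical(planted$suppression, unname(sim$manifest$suppression[id]))
  }
  expect_identical(sim$manifest$seed, 9)
  expect_identical(sim$manifest$commission_coupling, sim$params$commission)
})
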