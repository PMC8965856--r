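---
title: "Quantitative EEG spectral dynamics as an attention biomarker: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG spectral dynamics as an attention biomarker: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegattn)
```

## The problem

Sustained attention suppresses the posterior alpha rhythm (8–12 Hz) of the
scalp EEG: when a person engages a vigilance task, alpha power drops
relative to eyes-closed rest ("alpha desynchronization").  In populations
with attention impairment — here, patients with Prader–Willi syndrome
(PWS), a genetic disorder in which attention problems are highly
prevalent — this task-related suppression is weaker.  The ratio of
attention-task alpha power to resting alpha power is therefore a candidate
neurophysiological attention biomarker: the lower the ratio, the stronger
the attention-related cortical engagement.

`qeegattn` implements that analysis end to end: Welch spectral
estimation at 1-Hz resolution, 0–50 Hz spectrum normalization, band
powers, the resting theta/beta ratio (TBR), the attention-to-resting
alpha power ratio, and the cohort statistics battery used to evaluate the
biomarker against behavioral attention scores (the nine T-scored
variables of a continuous performance test, CPT).  Because the clinical
recordings such studies are based on are generally not redistributable,
the package also contains a synthetic EEG + cohort generator that plants
known effects, so every downstream stage is testable without any data
download.

## Spectral model

Each analysis epoch is 60 s of multichannel EEG at 200 Hz, restricted to
the midline electrodes Fz, Cz, Pz.  The Welch estimator splits the epoch
into 1-s blocks with half overlap (119 blocks for 60 s), subtracts each
block's mean, applies a periodic Hann taper, and averages the modified
periodograms:

$$\hat P(f_k) \;=\; \frac{1}{S}\sum_{s=1}^{S}
  \frac{\left|\sum_n w_n\,x^{(s)}_n e^{-2\pi i k n/L}\right|^2}{L\sum_n w_n^2},
  \qquad k = 0,\dots,L/2,$$

with non-DC, non-Nyquist bins doubled (one-sided folding).  The
`sum(w^2)` compensation makes the estimator satisfy Parseval's relation:
summed over all bins, the spectrum of a demeaned signal reproduces its
variance (tested at 5% for white noise and 2% for an in-bin sinusoid).
At 1-s blocks and 1-Hz bins, power per bin and power density coincide
numerically, so no density convention needs to be chosen.

Numerical choices worth stating:

* **Block aggregation.** `aggregate = "mean"` (standard Welch) is the
  default; a `"sum"` option is provided.  The factor of 119 between them
  cancels in every normalized quantity, the TBR, and the alpha ratio, so
  only absolute power depends on it.
* **Mean subtraction per block** means bin 0 carries essentially no
  power; the 0–50 Hz normalization total nevertheless *includes* bin 0,
  so DC offsets in a recording cannot distort normalized spectra.
* **Bands are inclusive integer ranges** at 1-Hz resolution: theta 4–7,
  alpha 8–12, beta 13–25, plus delta 0–3 for simulation and
  per-frequency reporting.  Together with 26–50 they tile 0–50 exactly;
  frequencies are identified by their Hz value throughout, never by
  array index.
* **Degenerate inputs** fail loudly: epochs shorter than one block,
  non-finite samples, zero total power (normalization), zero beta power
  (TBR), zero resting alpha (alpha ratio).

The **normalized spectrum** divides each channel's per-bin power by its
total power over 0–50 Hz, giving fractions that sum to one; it is
invariant under positive rescaling of the input signal.  The **TBR** is
theta power over beta power and is identical on raw and normalized
spectra.  The **alpha ratio** divides attention-task alpha power by
resting alpha power per channel.  Whether a published analysis computes
it on raw or normalized alpha power is often ambiguous; both modes are
implemented (`ratio_mode` in `run_config()`), normalized is the pipeline
default (the normalization step immediately precedes the ratio in the
analysis it mirrors), and both modes are exercised by the tests.  With
the generator's shared-phase session pairs the raw-mode ratio recovers
the planted suppression directly, which is why the recovery tests use
raw mode.

## Cohort statistics

The statistics layer mirrors a small-cohort clinical comparison:

* **BMI z-scores** standardize BMI against an age- and sex-specific
  reference table (`(bmi - mean)/sd` in the matching band); overweight is
  z > 1, obesity z > 2, strictly.  The bundled reference
  (`inst/extdata/bmi_norms_synthetic.csv`) is a smooth synthetic stand-in
  labeled as such; substitute a real population table for substantive
  work.
* **Group comparisons** use the Mann–Whitney U test for continuous
  variables and the Pearson chi-square test (df = 1) for 2×2 tables.
  The chi-square applies *no* continuity correction by default: that
  variant reproduces the printed worked examples the package tests
  against (a 4/6 vs 5/5 sex split gives p = 0.653, a 7/3 vs 4/6
  overweight split p = 0.178); Yates' correction is a flag.  The
  Mann–Whitney uses the exact null distribution when both groups have
  n ≤ 10 and no ties (validated against full enumeration), else the
  tie-corrected normal approximation without continuity correction,
  matching common statistical-package output.
* **Spearman correlations** report rho as the Pearson correlation of
  average ranks, with a two-sided p from the t-approximation
  `t = rho * sqrt((n-2)/(1-rho^2))` on n−2 df.  This conversion
  reproduces the published worked examples (0.547 → 0.013,
  0.524 → 0.018, 0.534 → 0.015, 0.329 → 0.157 at n = 20); note that one
  published pair (0.506 → 0.027) is *not* reproduced by this or any
  standard conversion we tried (the t-approximation gives 0.023) — a
  documented discrepancy, possibly a tie correction or a typo at the
  source.  An exact-permutation p is available for n ≤ 8.
* **Per-frequency t-tests** compare normalized power between groups at
  each 0–50 Hz bin (pooled-variance by default, Welch as a flag); bins
  where both groups are constant are flagged degenerate rather than
  given a fabricated p.  No multiple-testing correction is applied by
  default, matching the analysis mirrored here; a Benjamini–Hochberg
  annotation is available and clearly an extension.
* **Stepwise regression** is SPSS-style forward selection with removal
  (enter at p < 0.05, remove at p > 0.10, both configurable) by OLS.
  Published "stepwise" tables often print coefficients for *all*
  candidate predictors, so the result carries both the selected model
  and the full-entry model; with both thresholds at 1 the procedure
  reproduces the full OLS fit exactly.  The regression's group indicator
  is coded control = 0, PWS = 1 and labeled "genotype", following the
  convention of the tables it mirrors (which conflate genotype with
  group); the coding is kept as printed and flagged here.

## The synthetic generator

`simulate_eeg_session()` builds each channel as a 1/f^β Gaussian
background (spectrally shaped white noise, β = 1, 4 µV RMS) plus four
narrow-band stochastic oscillators — delta (2 Hz, FWHM 1.5, 3 µV RMS),
theta (6, 2, 3), alpha (10, 2, 6), beta (20, 6, 2).  Oscillators are
band-limited filtered noise, not sinusoids, so alpha power fluctuates
naturally across the 1-s Welch blocks; the bandwidths keep ≥ 95% of each
oscillator's power inside its nominal integer band.  Attention-task
sessions multiply the alpha amplitude by `sqrt(1 - s)` — suppression is
planted on *power* — and, for controls only, multiply delta and theta
power by 1.5 (the reported low-frequency increase exists but its size is
not published; 1.5 makes the per-frequency test property testable and is
config-exposed).  Patients' attention sessions leave delta/theta
untouched.

Suppression draws: controls uniform on [0.60, 0.70] (the reported 60–70%
alpha power decrease); patients uniform on [0.05, 0.55] — centered on
the reported average 30% decrease, with a deliberately wide
interindividual spread reflecting the heterogeneity visible in
patient-level biomarker plots (some patients show almost no
suppression).  `simulate_participant_pair()` draws one set of component
realizations and composes both sessions from it, so the sessions share
phases and the raw-mode alpha oscillator power ratio equals 1 − s
exactly per realization; what the measured Cz ratio adds on top is the
background leakage into 8–12 Hz, which raises the measured means to
≈ 0.38 (s = 0.65) and ≈ 0.71 (s = 0.30) — the frozen expectations of the
recovery tests, measured from the generator itself.

`simulate_cohort()` adds the behavioral layer for two groups of 10:
truncated-normal ages (18.5 ± 8.0 vs 19.8 ± 5.8 years) and BMI
(25.7 ± 5.9 vs 23.6 ± 3.5), fixed-count sex (4/6 vs 5/5), genotype (6
deletion / 4 non-deletion) and intelligence margins (7 of 10 patients
moderate-to-severe, coded 2; the rest mild, coded 1; controls 0) — fixed
counts rather than binomial draws so small cohorts match the reference
margins exactly.  Seven CPT T-scores are drawn per-group normal with the
reference means/SDs.  Two are planted as couplings:

* commission T = 43.0 + 25.04 × (measured raw-mode Cz alpha ratio) + N(0, 6);
* omission T = 49.3 + 14.41 × intelligence + N(0, 5.7).

The slopes are the reference regression coefficients; the intercepts
anchor the implied group means to the reference group means (e.g.
49.3 + 14.41 × 1.7 ≈ 74 for patient omission); the noise SDs keep the
marginal ratio–commission rank correlation near the reported ≈ 0.55.
The commission coupling deliberately uses the *measured* ratio (the
generator runs the spectral pipeline on its own recordings), so
regression recovery of the slope has no attenuation bias from
measurement error.  Every planted value is recorded in a manifest.

What the generator does **not** emulate: eye-blink/EMG artifact
topographies, inter-channel correlation structure, non-stationarity
beyond the planted session effects, or any connection between the
directly drawn T-scores and the EEG.  Passing tests therefore establish
that the *pipeline* recovers what was planted under realistic spectral
structure — not that the biomarker separates real clinical groups.

## Pipeline, formats, determinism

`run_pipeline()` takes a `run_config()` and executes: input loading
(simulation, or EDF files plus a cohort CSV), clean-epoch selection,
Welch PSD, normalization, features, and the statistics battery, returning
a result bundle that `render_report()` writes as CSVs, JSON, and a
plain-text summary (mean ± SD, 3-decimal p-values).  Points of note:

* **Epoch selection** automates "visual artifact inspection" as an
  explicit rule: the contiguous 60-s window minimizing the fraction of
  samples exceeding ±100 µV on the electrodes of interest, earliest
  window on ties, failing if the best window exceeds the configured
  maximum fraction.  The rule is reported in the bundle's provenance.
* **EDF input/output** is a minimal self-contained implementation of the
  clinical interchange format (16-bit samples, 1-s records); round-trip
  error is bounded by one quantization step and the analyses are
  tolerant to it.  Start date/time fields are written as constants so
  repeated runs are byte-identical.
* **Sessions**: only the eyes-closed resting and attention-task sessions
  are consumed; other session tags are accepted on input and ignored.
  Signals are analyzed as recorded — no filtering, re-referencing, ICA,
  or montage transformation.
* **Determinism**: every random draw descends from the single master
  seed; the same (config, seed) produces byte-identical reports, and the
  test suite checks this at file level.

## Problem sizes used in the checks

The automated checks run the planted-suppression recovery at 20 seeds
per suppression level, the per-frequency localization at 15 replicates
of 6 + 6 participants, the cohort detection rate at 100 seeded cohorts,
and the slope recovery at 200 seeded cohorts of 10 + 10 — sizes chosen
so the Monte-Carlo error of each summary is small relative to its
acceptance band (the 200-cohort mean slope has a standard error of
≈ 1.4 against a ±2.5 band).  The default generator synthesizes only the
three midline electrodes the analysis consumes; the full 19-channel
montage is one parameter away (`channels = ELECTRODES_1020`).

## Known limitations

* The synthetic norm table and generator defaults are stand-ins where
  the reference values are unpublished (absolute EEG power scale,
  low-frequency boost size, coupling noise); all published-style outputs
  are scale-invariant by construction, so the arbitrary power scale does
  not leak into results.
* The stepwise procedure tests one predictor per step by its partial
  t-test; with heavily collinear candidates (here: group indicator vs
  alpha ratio) selected-model coefficients are unstable across seeds,
  which is why recovery checks read the full-entry coefficient.
* Exact Mann–Whitney and exact Spearman permutation modes are limited to
  small samples by design; larger samples use the standard
  approximations.
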